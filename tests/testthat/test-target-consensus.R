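# Seed-match detection, site merging, k-of-n consensus and
# binding-site-count prioritization.

test_that("reverse complement is alphabet-safe and an involution", {
  expect_equal(reverse_complement("TGACGTCA"), "TGACGTCA")  # palindrome
  expect_equal(reverse_complement("AAAA"), "TTTT")
  expect_equal(reverse_complement("UGAGGUAG"), "CTACCTCA")
  expect_equal(reverse_complement("ANNT"), "ANNT")
  expect_error(reverse_complement("ACGX"), class = "mircons_sequence_error")
  set.seed(11)
  for (i in 1:200) {
    s <- random_seq(sample(1:40, 1), c("A", "C", "G", "T", "N"))
    expect_identical(reverse_complement(reverse_complement(s)), s)
    expect_identical(reverse_complement(s), rc_oracle(s))
  }
})

test_that("seed sites match the hand-derived example and edge cases", {
  # let-7a-like: seed 2-8 GAGGUAG -> site CTACCTC(+A) on the UTR
  hits <- find_seed_sites("let7", "UGAGGUAGUAGGUUGUAUAGUU", "AAACTACCTCAAA")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 3L)
  expect_equal(hits$end, 11L)
  expect_equal(hits$site_type, "8mer")

  expect_equal(nrow(find_seed_sites("m", "UGAGGUAGUA", "ACGTA")), 0L)
  expect_error(find_seed_sites("m", "UGAGGUA", "ACGTACGT"),
               class = "mircons_sequence_error")
  # N never matches
  expect_equal(nrow(find_seed_sites("let7", "UGAGGUAGUAGGUUGUAUAGUU",
                                    "AAACTACCNCAAA")), 0L)
})

test_that("detector equals the all-window brute-force oracle", {
  set.seed(21)
  for (rep in 1:30) {
    mseq <- chartr("T", "U", random_seq(22))
    utr <- random_seq(300)
    got <- find_seed_sites("m", mseq, utr, gene = "g")
    want <- naive_seed_sites("m", mseq, utr, gene = "g")
    expect_equal(got[c("start", "end", "site_type")],
                 want[c("start", "end", "site_type")],
                 ignore_attr = TRUE)
  }
})

test_that("site types collapse to the strongest per locus", {
  m <- "UGAGGUAGUAGGUUGUAUAGUU"   # core6 TACCTC, m8 anchor C, A1 anchor A
  utr_6 <- paste0("GG", "TACCTC", "GG")
  utr_m8 <- paste0("G", "CTACCTC", "GG")
  utr_a1 <- paste0("GG", "TACCTCA", "G")
  expect_equal(find_seed_sites("m", m, utr_6)$site_type, "6mer")
  expect_equal(find_seed_sites("m", m, utr_m8)$site_type, "7mer-m8")
  expect_equal(find_seed_sites("m", m, utr_a1)$site_type, "7mer-A1")
})

test_that("prediction TSV round-trips and rejects bad coordinates", {
  sites <- data.frame(gene = c("g1", "g1", "g2"), mirna = c("a", "b", "a"),
                      start = c(5L, 40L, 0L), end = c(13L, 47L, 6L),
                      site_type = c("8mer", "7mer-m8", "6mer"),
                      predictor = c("p1", "p1", "p2"), score = 0,
                      stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_predictions(sites, f)
  back <- parse_predictions(f)
  expect_named(back, c("p1", "p2"))
  flat <- do.call(rbind, c(back, list(make.row.names = FALSE)))
  expect_equal(flat[order(flat$gene, flat$start),
                    c("gene", "mirna", "start", "end", "site_type")],
               sites[order(sites$gene, sites$start),
                     c("gene", "mirna", "start", "end", "site_type")],
               ignore_attr = TRUE)

  # unknown site type downgraded to "other"; end <= start rejected
  sites$site_type[1] <- "weird"
  write_predictions(sites, f)
  expect_true("other" %in% do.call(rbind, parse_predictions(f))$site_type)
  sites$end[2] <- sites$start[2]
  write_predictions(sites, f)
  expect_error(parse_predictions(f), "line 3",
               class = "mircons_parse_error")

  # empty file with header parses to an empty set
  writeLines(paste(c("predictor", "mirna_id", "gene_id", "utr_start",
                     "utr_end", "site_type", "score"), collapse = "\t"), f)
  expect_length(parse_predictions(f), 0L)
})

test_that("overlapping same-miRNA sites merge; different miRNAs never do", {
  two <- data.frame(gene = "g", mirna = "a", start = c(10L, 11L),
                    end = c(18L, 18L), site_type = "8mer",
                    predictor = c("p1", "p2"), stringsAsFactors = FALSE)
  m <- merge_sites(two)
  expect_equal(nrow(m), 1L)
  expect_equal(m$n_predictors, 2L)
  expect_equal(m[, c("start", "end")], data.frame(start = 10L, end = 18L),
               ignore_attr = TRUE)

  apart <- two; apart$start <- c(10L, 30L); apart$end <- c(18L, 38L)
  expect_equal(nrow(merge_sites(apart)), 2L)

  crossmir <- two; crossmir$mirna <- c("a", "b")
  expect_equal(nrow(merge_sites(crossmir)), 2L)

  # touching intervals do not merge (overlap must be >= 1 nt)
  touching <- two; touching$start <- c(10L, 18L); touching$end <- c(18L, 25L)
  expect_equal(nrow(merge_sites(touching)), 2L)
})

test_that("merging is idempotent, order-invariant and equals the naive
           pairwise-union oracle on jittered call sets", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(3:25, 1)
    sites <- data.frame(
      gene = "g", mirna = sample(c("a", "b", "c"), n, replace = TRUE),
      start = sample(0:120, n, replace = TRUE), site_type = "6mer",
      predictor = sample(paste0("p", 1:4), n, replace = TRUE),
      stringsAsFactors = FALSE)
    sites$end <- sites$start + sample(6:8, n, replace = TRUE)
    m1 <- merge_sites(sites)
    # idempotence (re-merge using the merged sites as single-predictor rows)
    rein <- m1; rein$predictor <- rein$predictors
    m2 <- merge_sites(rein[names(sites)])
    expect_equal(m2[c("start", "end", "mirna")], m1[c("start", "end", "mirna")])
    # permutation invariance
    mp <- merge_sites(sites[sample(n), ])
    expect_equal(mp, m1)
    # per-pair counts equal the naive fixpoint union
    got <- table(paste(m1$gene, m1$mirna, sep = "\r"))
    want <- naive_merge_counts(sites)
    expect_equal(as.integer(got[names(want)]), as.integer(want))
  }
})

test_that("k-of-n consensus keeps a pair iff >= k predictors support it", {
  mk <- function(pred, gene, mirna, start) {
    data.frame(gene = gene, mirna = mirna, start = start,
               end = start + 7L, site_type = "7mer-m8", predictor = pred,
               stringsAsFactors = FALSE)
  }
  calls <- list(p1 = rbind(mk("p1", "g1", "a", 10L), mk("p1", "g2", "b", 5L)),
                p2 = rbind(mk("p2", "g1", "a", 11L)),
                p3 = rbind(mk("p3", "g1", "a", 10L), mk("p3", "g2", "b", 5L)))
  # k = 1: union of pairs
  expect_equal(nrow(consensus_interactions(calls, 1)$pairs), 2L)
  # k = n: one silent predictor drops the pair
  full <- consensus_interactions(calls, 3)
  expect_equal(full$pairs$gene, "g1")
  expect_equal(full$pairs$n_sites, 1L)   # 10-18 and 11-18 merge
  # whitelist restricts the predictor universe (relaxed two-tool mode)
  relax <- consensus_interactions(calls, 2, predictors = c("p1", "p3"))
  expect_setequal(relax$pairs$gene, c("g1", "g2"))
  expect_error(consensus_interactions(calls, 4),
               class = "mircons_parameter_error")
})

test_that("consensus equals brute-force set algebra over random support", {
  set.seed(41)
  preds <- paste0("p", 1:3)
  for (rep in 1:10) {
    pairs <- expand.grid(gene = paste0("g", 1:5), mirna = c("a", "b"),
                         stringsAsFactors = FALSE)
    support <- matrix(runif(nrow(pairs) * 3) < 0.5, ncol = 3,
                      dimnames = list(NULL, preds))
    calls <- lapply(preds, function(p) {
      sel <- which(support[, p])
      if (!length(sel)) {
        return(data.frame(gene = character(0), mirna = character(0),
                          start = integer(0), end = integer(0),
                          site_type = character(0), predictor = character(0),
                          stringsAsFactors = FALSE))
      }
      data.frame(gene = pairs$gene[sel], mirna = pairs$mirna[sel],
                 start = 10L, end = 17L, site_type = "7mer-m8",
                 predictor = p, stringsAsFactors = FALSE)
    })
    names(calls) <- preds
    for (k in 1:3) {
      got <- consensus_interactions(calls, k)$pairs
      want <- pairs[rowSums(support) >= k, ]
      expect_equal(nrow(got), nrow(want))
      expect_setequal(paste(got$gene, got$mirna),
                      paste(want$gene, want$mirna))
      # monotonicity in k is implied: each k checked against set algebra
    }
  }
})

test_that("prioritization filters by total merged sites and ranks
           deterministically", {
  pairs <- data.frame(
    gene = c("A", "A", "B", "C"), mirna = c("m1", "m2", "m1", "m1"),
    n_predictors = 5L, predictors = "p1,p2,p3,p4,p5",
    n_sites = c(3L, 2L, 4L, 3L), stringsAsFactors = FALSE)
  got <- prioritize_targets(pairs, min_sites = 4)
  expect_equal(got$genes$gene, c("A", "B"))   # 5 sites > 4 sites
  expect_equal(got$genes$total_sites, c(5L, 4L))
  expect_equal(got$genes$rank, 1:2)
  expect_equal(prioritize_targets(pairs[0, ], 4)$genes$gene, character(0))
  # distinct-miRNA counting mode
  alt <- prioritize_targets(pairs, min_sites = 2, count = "distinct_mirnas")
  expect_equal(alt$genes$gene[1], "A")
  expect_equal(nrow(alt$genes), 1L)
  # exclusion list (case-insensitive)
  excl <- prioritize_targets(pairs, min_sites = 4, exclude = "a")
  expect_equal(excl$genes$gene, "B")
})
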
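# Seed-match target-site detection, cross-predictor consensus and
# binding-site-count prioritization.
#
# Site taxonomy is the canonical one: the seed is miRNA positions 2-7
# (6mer) or 2-8 (7mer-m8), matched by Watson-Crick reverse complement on
# the UTR sense strand; an A in the UTR opposite miRNA position 1 upgrades
# a site to 7mer-A1 / 8mer. Each locus is reported once with its strongest
# type (8mer > 7mer-m8 > 7mer-A1 > 6mer). All coordinates are 0-based
# half-open on the UTR 5'->3' strand.

SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1", "6mer")

#' Reverse complement of a DNA/RNA string
#'
#' `U` is normalized to `T` before complementing, so the result is always
#' DNA; `N` maps to `N`. The operation is an involution after U->T
#' normalization.
#'
#' @param seq a single character string over `ACGTUN` (either case).
#' @return the reverse complement, upper-case DNA.
#' @examples
#' reverse_complement("TGACGTCA")   # palindrome: returns itself
#' reverse_complement("UGAGGUAG")
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- chartr("u", "U", toupper(seq))
  s <- chartr("U", "T", s)
  if (grepl("[^ACGTN]", s)) {
    stop_mircons("mircons_sequence_error",
                 "sequence contains characters outside ACGTUN")
  }
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

# normalize a nucleotide string to upper-case DNA, validating the alphabet
normalize_dna <- function(seq, allow_n = TRUE, what = "sequence") {
  s <- chartr("U", "T", toupper(seq))
  pat <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  if (grepl(pat, s)) {
    stop_mircons("mircons_sequence_error", what,
                 " contains characters outside the ",
                 if (allow_n) "ACGTUN" else "ACGTU", " alphabet")
  }
  s
}

# exact positions (0-based starts) of `pattern` in `subject`, overlapping
# occurrences included; an N in the subject never matches.
match_starts <- function(subject, pattern) {
  ls <- nchar(subject); lp <- nchar(pattern)
  if (ls < lp) return(integer(0))
  hits <- Biostrings::matchPattern(pattern, Biostrings::DNAString(subject),
                                   fixed = TRUE)
  BiocGenerics::start(hits) - 1L
}

#' Detect canonical miRNA seed-match sites on a 3'UTR
#'
#' Scans the UTR sense strand for the reverse complement of the miRNA seed.
#' Matches of positions 2-7 define the 6mer core; an additional match to
#' position 8 (5' of the core on the UTR) and/or an `A` opposite position 1
#' (3' of the core) upgrade the locus to 7mer-m8, 7mer-A1 or 8mer. Each
#' 6mer core locus is reported exactly once, with its strongest type.
#'
#' @param mirna_id miRNA identifier used in the output.
#' @param mirna_seq miRNA sequence, 5'->3', `ACGU` (or DNA), length >= 8.
#' @param utr UTR sequence over `ACGTN`; `N` never matches.
#' @param gene gene identifier for the output (default `NA`).
#' @param site_types subset of `c("8mer","7mer-m8","7mer-A1","6mer")` to
#'   report (after strongest-type resolution).
#' @param predictor predictor label recorded on each site.
#' @return a data frame of binding sites with columns `gene`, `mirna`,
#'   `start`, `end` (0-based half-open), `site_type`, `predictor`, sorted
#'   by `(start, mirna)`.
#' @examples
#' find_seed_sites("let7", "UGAGGUAGUAGGUUGUAUAGUU", "AAACTACCTCAAA")
#' @export
find_seed_sites <- function(mirna_id, mirna_seq, utr, gene = NA_character_,
                            site_types = SITE_TYPES,
                            predictor = "seedmatch") {
  m <- normalize_dna(mirna_seq, allow_n = FALSE, what = "miRNA sequence")
  if (nchar(m) < 8L) {
    stop_mircons("mircons_sequence_error", "miRNA '", mirna_id,
                 "' is shorter than 8 nt")
  }
  u <- normalize_dna(utr, allow_n = TRUE, what = "UTR sequence")
  site_types <- match.arg(site_types, SITE_TYPES, several.ok = TRUE)
  L <- nchar(u)

  core6 <- reverse_complement(substr(m, 2L, 7L))       # 6 nt
  m8c <- reverse_complement(substr(m, 8L, 8L))         # 1 nt, 5' of core

  empty <- data.frame(gene = character(0), mirna = character(0),
                      start = integer(0), end = integer(0),
                      site_type = character(0), predictor = character(0),
                      stringsAsFactors = FALSE)
  if (L < 6L) return(empty)

  uc <- strsplit(u, "", fixed = TRUE)[[1L]]
  starts <- match_starts(u, core6)                     # core positions j
  if (!length(starts)) return(empty)

  out <- lapply(starts, function(j) {                  # j is 0-based
    has_m8 <- j >= 1L && uc[j] == m8c                  # uc[j] is pos j-1
    has_a1 <- j + 6L < L && uc[j + 7L] == "A"
    if (has_m8 && has_a1) {
      c(j - 1L, j + 7L, "8mer")
    } else if (has_m8) {
      c(j - 1L, j + 6L, "7mer-m8")
    } else if (has_a1) {
      c(j, j + 7L, "7mer-A1")
    } else {
      c(j, j + 6L, "6mer")
    }
  })
  res <- data.frame(gene = gene, mirna = mirna_id,
                    start = as.integer(vapply(out, `[`, "", 1L)),
                    end = as.integer(vapply(out, `[`, "", 2L)),
                    site_type = vapply(out, `[`, "", 3L),
                    predictor = predictor, stringsAsFactors = FALSE)
  res <- res[res$site_type %in% site_types, , drop = FALSE]
  res <- res[order(res$start, res$mirna), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Detect seed sites for many miRNAs over many UTRs
#'
#' @param mirnas named character vector of miRNA sequences (5'->3').
#' @param utrs named character vector of UTR sequences.
#' @inheritParams find_seed_sites
#' @return one data frame of binding sites (see [find_seed_sites()]).
#' @export
scan_utrs <- function(mirnas, utrs, site_types = SITE_TYPES,
                      predictor = "seedmatch") {
  stopifnot(!is.null(names(mirnas)), !is.null(names(utrs)))
  res <- list()
  for (g in names(utrs)) {
    for (mi in names(mirnas)) {
      res[[length(res) + 1L]] <-
        find_seed_sites(mi, mirnas[[mi]], utrs[[g]], gene = g,
                        site_types = site_types, predictor = predictor)
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- find_seed_sites("x", "ACGUACGU", "", gene = "x")[0, ]
  }
  out <- out[order(out$gene, out$start, out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read predictor site calls from a TSV file
#'
#' Expected header: `predictor`, `mirna_id`, `gene_id`, `utr_start`,
#' `utr_end`, `site_type`, `score`; coordinates 0-based half-open. Unknown
#' site types are recorded as `"other"` (they participate in consensus but
#' not in the type hierarchy).
#'
#' @param path TSV file path.
#' @return a named list (one element per predictor label) of binding-site
#'   data frames in the [find_seed_sites()] layout plus a `score` column.
#' @export
parse_predictions <- function(path) {
  req <- c("predictor", "mirna_id", "gene_id", "utr_start", "utr_end",
           "site_type", "score")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  missing <- setdiff(req, names(tab))
  if (length(missing)) {
    stop_mircons("mircons_parse_error", "missing column(s): ",
                 paste(missing, collapse = ", "))
  }
  n <- nrow(tab)
  start <- suppressWarnings(as.integer(tab$utr_start))
  end <- suppressWarnings(as.integer(tab$utr_end))
  bad <- which(is.na(start) | is.na(end) | start < 0 | end <= start)
  if (length(bad)) {
    stop_mircons("mircons_parse_error",
                 "invalid coordinates (need 0 <= start < end) at line ",
                 bad[1L] + 1L)  # +1 for the header line
  }
  st <- ifelse(tab$site_type %in% SITE_TYPES, tab$site_type, "other")
  sites <- data.frame(gene = tab$gene_id, mirna = tab$mirna_id,
                      start = start, end = end, site_type = st,
                      predictor = tab$predictor,
                      score = suppressWarnings(as.numeric(tab$score)),
                      stringsAsFactors = FALSE)
  split(sites, sites$predictor)
}

#' Write predictor site calls to TSV
#'
#' Inverse of [parse_predictions()].
#'
#' @param sites a binding-site data frame (columns `gene`, `mirna`,
#'   `start`, `end`, `site_type`, `predictor`, optionally `score`).
#' @param path output file path.
#' @export
write_predictions <- function(sites, path) {
  out <- data.frame(predictor = sites$predictor, mirna_id = sites$mirna,
                    gene_id = sites$gene, utr_start = sites$start,
                    utr_end = sites$end, site_type = sites$site_type,
                    score = if ("score" %in% names(sites)) sites$score else 0,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

site_type_rank <- function(x) {
  r <- match(x, SITE_TYPES)         # 1 strongest
  r[is.na(r)] <- length(SITE_TYPES) + 1L  # "other" weakest
  r
}

#' Merge overlapping binding sites of the same miRNA
#'
#' Sites on one gene reported for the same miRNA whose intervals overlap by
#' at least 1 nt are merged into one site spanning their union; supporting
#' predictor labels are unioned and the strongest site type is kept. Sites
#' of different miRNAs never merge. The result is deterministic, sorted by
#' `(start, mirna)`, and idempotent under re-merging.
#'
#' @param sites binding-site data frame for a single gene.
#' @return data frame with columns `gene`, `mirna`, `start`, `end`,
#'   `site_type`, `predictors` (comma-joined, sorted), `n_predictors`.
#' @export
merge_sites <- function(sites) {
  if (nrow(sites) == 0L) {
    return(data.frame(gene = character(0), mirna = character(0),
                      start = integer(0), end = integer(0),
                      site_type = character(0), predictors = character(0),
                      n_predictors = integer(0), stringsAsFactors = FALSE))
  }
  if (length(unique(sites$gene)) > 1L) {
    stop_mircons("mircons_parameter_error",
                 "merge_sites expects sites of a single gene")
  }
  res <- list()
  for (mi in sort(unique(sites$mirna))) {
    s <- sites[sites$mirna == mi, , drop = FALSE]
    s <- s[order(s$start, s$end), , drop = FALSE]
    cur_start <- s$start[1L]; cur_end <- s$end[1L]
    cur_pred <- s$predictor[1L]; cur_type <- s$site_type[1L]
    flush <- function() {
      preds <- sort(unique(cur_pred))
      data.frame(gene = s$gene[1L], mirna = mi, start = cur_start,
                 end = cur_end, site_type = cur_type,
                 predictors = paste(preds, collapse = ","),
                 n_predictors = length(preds), stringsAsFactors = FALSE)
    }
    if (nrow(s) > 1L) {
      for (i in 2:nrow(s)) {
        if (s$start[i] < cur_end) {        # >= 1 nt overlap
          cur_end <- max(cur_end, s$end[i])
          cur_pred <- c(cur_pred, s$predictor[i])
          if (site_type_rank(s$site_type[i]) < site_type_rank(cur_type)) {
            cur_type <- s$site_type[i]
          }
        } else {
          res[[length(res) + 1L]] <- flush()
          cur_start <- s$start[i]; cur_end <- s$end[i]
          cur_pred <- s$predictor[i]; cur_type <- s$site_type[i]
        }
      }
    }
    res[[length(res) + 1L]] <- flush()
  }
  out <- do.call(rbind, res)
  out <- out[order(out$start, out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' k-of-n consensus over predictor call sets
#'
#' A gene-miRNA pair is retained iff at least `k` predictors report at
#' least one site for it (full consensus: `k` = number of predictors).
#' Merged site counts for retained pairs are computed with
#' [merge_sites()] over the union of the supporting predictors' calls.
#'
#' @param calls named list of binding-site data frames, one per predictor,
#'   or a single data frame with a `predictor` column.
#' @param k required number of supporting predictors.
#' @param predictors optional whitelist: only these predictors are
#'   considered at all (the relaxed two-algorithm mode).
#' @param gene_level if `TRUE`, a gene is retained when >= `k` predictors
#'   report any site on it, regardless of miRNA (default pair-level).
#' @return a list with `pairs` (data frame: `gene`, `mirna`,
#'   `n_predictors`, `predictors`, `n_sites`) and `sites` (merged sites of
#'   retained pairs).
#' @export
consensus_interactions <- function(calls, k, predictors = NULL,
                                   gene_level = FALSE) {
  if (is.data.frame(calls)) calls <- split(calls, calls$predictor)
  if (!is.null(predictors)) calls <- calls[names(calls) %in% predictors]
  n_pred <- length(calls)
  k <- check_positive_int(k, "k")
  if (n_pred < 1L || k > n_pred) {
    stop_mircons("mircons_parameter_error",
                 "k must satisfy 1 <= k <= number of predictors (",
                 n_pred, ")")
  }
  all_sites <- do.call(rbind, c(calls, list(make.row.names = FALSE)))
  empty_pairs <- data.frame(gene = character(0), mirna = character(0),
                            n_predictors = integer(0),
                            predictors = character(0),
                            n_sites = integer(0), stringsAsFactors = FALSE)
  if (is.null(all_sites) || nrow(all_sites) == 0L) {
    return(list(pairs = empty_pairs, sites = merge_sites(all_sites[0, ])))
  }

  key <- if (gene_level) all_sites$gene else {
    paste(all_sites$gene, all_sites$mirna, sep = "\r")
  }
  support <- tapply(all_sites$predictor, key,
                    function(p) sort(unique(p)), simplify = FALSE)
  keep_keys <- names(support)[vapply(support, length, 0L) >= k]
  if (gene_level) {
    keep <- all_sites$gene %in% keep_keys
  } else {
    keep <- key %in% keep_keys
  }
  kept <- all_sites[keep, , drop = FALSE]
  if (nrow(kept) == 0L) {
    return(list(pairs = empty_pairs, sites = merge_sites(kept)))
  }
  merged <- do.call(rbind, lapply(split(kept, kept$gene), merge_sites))
  rownames(merged) <- NULL
  pk <- paste(merged$gene, merged$mirna, sep = "\r")
  agg <- tapply(seq_len(nrow(merged)), pk, function(i) {
    data.frame(gene = merged$gene[i[1L]], mirna = merged$mirna[i[1L]],
               n_sites = length(i), stringsAsFactors = FALSE)
  }, simplify = FALSE)
  pairs <- do.call(rbind, agg)
  sup_key <- if (gene_level) pairs$gene else {
    paste(pairs$gene, pairs$mirna, sep = "\r")
  }
  pairs$n_predictors <- vapply(support[sup_key], length, 0L)
  pairs$predictors <- vapply(support[sup_key], paste, "", collapse = ",")
  pairs <- pairs[order(pairs$gene, pairs$mirna),
                 c("gene", "mirna", "n_predictors", "predictors", "n_sites")]
  rownames(pairs) <- NULL
  merged <- merged[order(merged$gene, merged$start, merged$mirna), ,
                   drop = FALSE]
  rownames(merged) <- NULL
  list(pairs = pairs, sites = merged)
}

#' Prioritize consensus targets by merged binding-site count
#'
#' Genes with at least `min_sites` merged binding sites (summed over
#' miRNAs, or distinct supporting miRNAs when `count = "distinct_mirnas"`)
#' are retained and ranked by total sites descending, then by number of
#' distinct miRNAs descending, then gene id.
#'
#' @param consensus result of [consensus_interactions()] (or a `pairs`
#'   data frame with `gene`, `mirna`, `n_sites`).
#' @param min_sites minimum site count to retain a gene (study default 4).
#' @param count `"total"` (default: total merged sites) or
#'   `"distinct_mirnas"`.
#' @param exclude optional character vector of gene ids to drop (e.g.
#'   genes involved in miRNA function itself).
#' @return a list with `genes` (ranked data frame: `gene`, `total_sites`,
#'   `n_mirnas`, `rank`) and `breakdown` (gene x miRNA merged-site count
#'   matrix for the retained genes).
#' @export
prioritize_targets <- function(consensus, min_sites = 4,
                               count = c("total", "distinct_mirnas"),
                               exclude = NULL) {
  count <- match.arg(count)
  pairs <- if (is.data.frame(consensus)) consensus else consensus$pairs
  min_sites <- check_positive_int(min_sites, "min_sites")
  empty <- list(genes = data.frame(gene = character(0),
                                   total_sites = integer(0),
                                   n_mirnas = integer(0), rank = integer(0),
                                   stringsAsFactors = FALSE),
                breakdown = matrix(0L, 0, 0))
  if (nrow(pairs) == 0L) return(empty)
  if (!is.null(exclude)) {
    pairs <- pairs[!(toupper(pairs$gene) %in% toupper(exclude)), ,
                   drop = FALSE]
    if (nrow(pairs) == 0L) return(empty)
  }
  total <- tapply(pairs$n_sites, pairs$gene, sum)
  nmir <- tapply(pairs$mirna, pairs$gene, function(m) length(unique(m)))
  genes <- data.frame(gene = names(total),
                      total_sites = as.integer(total),
                      n_mirnas = as.integer(nmir[names(total)]),
                      stringsAsFactors = FALSE)
  score <- if (count == "total") genes$total_sites else genes$n_mirnas
  genes <- genes[score >= min_sites, , drop = FALSE]
  if (nrow(genes) == 0L) return(empty)
  o <- order(-genes$total_sites, -genes$n_mirnas, genes$gene)
  genes <- genes[o, , drop = FALSE]
  genes$rank <- seq_len(nrow(genes))
  rownames(genes) <- NULL
  sub <- pairs[pairs$gene %in% genes$gene, , drop = FALSE]
  mirs <- sort(unique(sub$mirna))
  breakdown <- matrix(0L, nrow(genes), length(mirs),
                      dimnames = list(genes$gene, mirs))
  for (i in seq_len(nrow(sub))) {
    breakdown[sub$gene[i], sub$mirna[i]] <- sub$n_sites[i]
  }
  list(genes = genes, breakdown = breakdown)
}
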
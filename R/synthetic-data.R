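# Ground-truth synthetic data generators for every pipeline input:
# two-colour array intensities (Normal background + Exponential signal,
# the normexp generative model), qPCR Cp tables (generative inverse of
# delta-delta-Ct), 3'UTRs with planted seed-match sites, pseudo-predictor
# call sets, promoters with planted CRE elements, and phenotypes coupled
# to chosen genes.
#
# Determinism contract: one master integer seed per generator call, split
# into independent sub-streams by stable hashing (substream_seed), so the
# same seed is bit-identical on rerun.

#' Simulate a two-colour miRNA array experiment
#'
#' Each spot's foreground intensity is a Normal background draw plus an
#' Exponential signal draw. Differential probes carry a signed log2
#' channel-ratio effect in treated arrays, split symmetrically across the
#' two dyes (+/- effect/2) so that M stays centred for normalization. A
#' small set of control probes (the "RNU6B" role) has true ratio 0.
#'
#' @param n_probes number of probes (the study platform carried 580).
#' @param n_arrays number of arrays; the first half are labelled
#'   `treated`, the rest `control`.
#' @param de_fraction fraction of probes that are truly differential;
#'   the DE count is `round(de_fraction * n_probes)`.
#' @param effect_log2 absolute true log2 ratio of DE probes (a random sign
#'   is drawn per probe).
#' @param bg_mean,bg_sd Normal background mean and sd (intensity units).
#' @param signal_mean Exponential signal mean (intensity units).
#' @param n_control number of control probes (never DE).
#' @param seed master integer seed.
#' @return an object of class `array_sim`: matrices `fg_r`, `fg_g`,
#'   `bg_r`, `bg_g` (probe x array), `probe_ids`, `control_probe_ids`,
#'   `group_labels`, `truth` (data frame `probe_id`, `true_log2_ratio`,
#'   `is_de`), `params`, `seed`.
#' @export
simulate_two_color_array <- function(n_probes, n_arrays, de_fraction = 0.06,
                                     effect_log2 = 2, bg_mean = 100,
                                     bg_sd = 15, signal_mean = 200,
                                     n_control = 4, seed = 1) {
  n_probes <- check_positive_int(n_probes, "n_probes")
  n_arrays <- check_positive_int(n_arrays, "n_arrays")
  de_fraction <- check_fraction(de_fraction, "de_fraction")
  bg_mean <- check_positive_real(bg_mean, "bg_mean")
  bg_sd <- check_positive_real(bg_sd, "bg_sd")
  signal_mean <- check_positive_real(signal_mean, "signal_mean")
  if (n_control >= n_probes) {
    stop_mircons("mircons_parameter_error",
                 "n_control must be smaller than n_probes")
  }

  probe_ids <- sprintf("probe_%05d", seq_len(n_probes))
  control_ids <- if (n_control > 0) {
    probe_ids[seq_len(n_control)] <- sprintf("ctrl_%02d", seq_len(n_control))
    probe_ids[seq_len(n_control)]
  } else character(0)
  groups <- rep(c("treated", "control"),
                c(ceiling(n_arrays / 2), floor(n_arrays / 2)))
  names(groups) <- sprintf("array_%02d", seq_len(n_arrays))

  n_de <- round(de_fraction * n_probes)
  if (n_de > n_probes - n_control) {
    stop_mircons("mircons_parameter_error",
                 "de_fraction leaves no room for control probes")
  }
  truth <- data.frame(probe_id = probe_ids,
                      true_log2_ratio = 0, is_de = FALSE,
                      stringsAsFactors = FALSE)
  with_seed(substream_seed(seed, "de_assignment"), {
    eligible <- setdiff(seq_len(n_probes), seq_len(n_control))
    de_idx <- if (n_de > 0) sample(eligible, n_de) else integer(0)
    signs <- sample(c(-1, 1), n_de, replace = TRUE)
  })
  truth$is_de[de_idx] <- TRUE
  truth$true_log2_ratio[de_idx] <- signs * effect_log2

  # per-channel expected signal: ratio 2^tau in treated arrays, split +-tau/2
  tau <- matrix(0, n_probes, n_arrays)
  tau[, groups == "treated"] <- truth$true_log2_ratio
  mean_r <- signal_mean * 2^(tau / 2)
  mean_g <- signal_mean * 2^(-tau / 2)

  rnorm_pos <- function(n, mean, sd) {   # resample the rare negatives
    x <- stats::rnorm(n, mean, sd)
    while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
    x
  }
  draw <- function(label, means) {
    with_seed(substream_seed(seed, label), {
      bg <- matrix(rnorm_pos(n_probes * n_arrays, bg_mean, bg_sd),
                   n_probes, n_arrays)
      sig <- matrix(stats::rexp(n_probes * n_arrays, rate = 1 / means),
                    n_probes, n_arrays)
      list(bg = bg, fg = bg + sig)
    })
  }
  # rexp rate recycles element-wise over the matrix of means
  red <- draw("red", as.vector(mean_r))
  green <- draw("green", as.vector(mean_g))

  dn <- list(probe_ids, names(groups))
  out <- list(fg_r = `dimnames<-`(red$fg, dn),
              fg_g = `dimnames<-`(green$fg, dn),
              bg_r = `dimnames<-`(red$bg, dn),
              bg_g = `dimnames<-`(green$bg, dn),
              probe_ids = probe_ids, control_probe_ids = control_ids,
              group_labels = groups, truth = truth,
              params = list(de_fraction = de_fraction,
                            effect_log2 = effect_log2, bg_mean = bg_mean,
                            bg_sd = bg_sd, signal_mean = signal_mean),
              seed = seed)
  class(out) <- "array_sim"
  out
}

#' Simulate a qPCR crossing-point table with known fold changes
#'
#' Generative inverse of delta-delta-Ct: one expression doubling lowers Cp
#' by one cycle. Per-sample loading offsets affect all genes (including the
#' reference) and cancel in dCp; measurement noise is i.i.d. Normal per
#' well.
#'
#' @param genes character vector of gene ids (must include
#'   `reference_gene`).
#' @param n_per_group samples per group (the study used 5 mice per group).
#' @param true_log2fc named numeric of true log2 fold changes (treated vs
#'   control); the reference gene must have value 0 (missing genes
#'   default to 0).
#' @param cp_noise_sd per-well Cp noise sd (cycles).
#' @param reference_gene reference gene id (the "HPRT"/"sno-234" role).
#' @param seed master integer seed.
#' @return class `cp_sim`: a [cp_table()] plus `truth` (named numeric of
#'   true log2 fold changes) and `seed`.
#' @export
simulate_cp_table <- function(genes, n_per_group = 5, true_log2fc = numeric(0),
                              cp_noise_sd = 0.2, reference_gene = genes[1L],
                              seed = 1) {
  n_per_group <- check_positive_int(n_per_group, "n_per_group")
  if (!reference_gene %in% genes) {
    stop_mircons("mircons_config_error",
                 "reference gene '", reference_gene, "' not among genes")
  }
  if (cp_noise_sd < 0) {
    stop_mircons("mircons_parameter_error", "cp_noise_sd must be >= 0")
  }
  fc <- stats::setNames(rep(0, length(genes)), genes)
  fc[names(true_log2fc)] <- true_log2fc
  if (fc[[reference_gene]] != 0) {
    stop_mircons("mircons_config_error",
                 "reference gene must have true_log2fc = 0")
  }
  n <- 2L * n_per_group
  samples <- sprintf("sample_%02d", seq_len(n))
  group <- stats::setNames(rep(c("treated", "control"), each = n_per_group),
                           samples)
  with_seed(substream_seed(seed, "cp"), {
    base <- stats::runif(length(genes), 18, 28)        # per-gene baseline Cp
    loading <- stats::rnorm(n, 0, 0.5)                 # per-sample offset
    noise <- matrix(stats::rnorm(n * length(genes), 0, cp_noise_sd),
                    n, length(genes))
  })
  eff <- outer(group == "treated", fc, function(tr, f) -tr * f)
  cp <- matrix(base, n, length(genes), byrow = TRUE) + loading + eff + noise
  dimnames(cp) <- list(samples, genes)
  out <- cp_table(cp, group, reference_gene)
  out$truth <- fc
  out$seed <- seed
  class(out) <- c("cp_sim", class(out))
  out
}

# uniform iid A/C/G/T string
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# non-overlapping start positions for `widths` blocks in [0, len), kept
# >= gap nt apart; NULL when a placement attempt fails
place_blocks <- function(widths, len, gap = 2L, max_try = 200L) {
  for (t in seq_len(max_try)) {
    starts <- sort(sample.int(len - max(widths) + 1L, length(widths)) - 1L)
    o <- order(starts)
    ok <- TRUE
    end_prev <- -gap - 1L
    for (i in seq_along(starts)) {
      if (starts[i] < end_prev + gap) { ok <- FALSE; break }
      end_prev <- starts[i] + widths[o][i]
    }
    if (ok) return(starts)
  }
  NULL
}

#' Simulate 3'UTRs with planted miRNA seed-match sites
#'
#' Backgrounds are rejection-sampled uniform i.i.d. A/C/G/T until they are
#' free of accidental seed matches for every listed miRNA, then 8mer sites
#' (seed match plus the A1 anchor) are planted at the requested per-gene
#' counts with >= 2 nt spacers; the full sequence is re-checked after
#' planting so the truth sites are exactly the detectable sites.
#'
#' @param n_genes number of genes.
#' @param utr_length UTR length (nt).
#' @param mirnas named character vector of miRNA sequences (5'->3',
#'   `ACGU`, >= 8 nt).
#' @param planted_counts named list: gene id -> named integer vector
#'   (miRNA id -> site count). Gene ids not listed get zero sites; gene
#'   ids are `gene_001`, ... `gene_<n>` unless the list names say
#'   otherwise (extra names are appended as additional genes).
#' @param seed master integer seed.
#' @return class `utr_sim`: `utr_sequences` (named character),
#'   `mirnas`, `truth_sites` (data frame `gene`, `mirna`, `start`, `end`,
#'   `site_type`), `seed`.
#' @export
simulate_utr_set <- function(n_genes, utr_length, mirnas,
                             planted_counts = list(), seed = 1) {
  n_genes <- check_positive_int(n_genes, "n_genes")
  utr_length <- check_positive_int(utr_length, "utr_length")
  stopifnot(!is.null(names(mirnas)))
  for (mi in names(mirnas)) {
    if (nchar(mirnas[[mi]]) < 8L) {
      stop_mircons("mircons_parameter_error", "miRNA '", mi,
                   "' must be >= 8 nt")
    }
  }
  gene_ids <- sprintf("gene_%03d", seq_len(n_genes))
  extra <- setdiff(names(planted_counts), gene_ids)
  gene_ids <- c(gene_ids, extra)

  # 8mer planted site sequence for a miRNA: revcomp(pos 2-8) + A1 anchor
  site_seq <- vapply(mirnas, function(m) {
    paste0(reverse_complement(substr(normalize_dna(m, FALSE), 2L, 8L)), "A")
  }, "")

  utrs <- character(0)
  truth <- list()
  with_seed(substream_seed(seed, "utr"), {
    for (g in gene_ids) {
      cnt <- planted_counts[[g]]
      cnt <- cnt[!is.na(cnt) & cnt > 0]
      plant_mirs <- rep(names(cnt), times = as.integer(cnt))
      need <- sum(nchar(site_seq[plant_mirs])) + 2L * length(plant_mirs)
      if (need >= utr_length) {
        stop_mircons("mircons_planting_error", "gene '", g,
                     "': planted sites (", need,
                     " nt incl. spacers) do not fit in ", utr_length, " nt")
      }
      for (try in seq_len(10000L)) {
        s <- random_dna(utr_length)
        if (length(plant_mirs)) {
          starts <- place_blocks(rep(8L, length(plant_mirs)), utr_length)
          if (is.null(starts)) next
          ord <- sample(seq_along(plant_mirs))   # random miRNA-to-slot map
          chars <- strsplit(s, "", fixed = TRUE)[[1L]]
          for (i in seq_along(starts)) {
            mi <- plant_mirs[ord[i]]
            chars[(starts[i] + 1L):(starts[i] + 8L)] <-
              strsplit(site_seq[[mi]], "", fixed = TRUE)[[1L]]
          }
          s <- paste(chars, collapse = "")
          planted <- data.frame(gene = g, mirna = plant_mirs[ord],
                                start = starts, end = starts + 8L,
                                site_type = "8mer", stringsAsFactors = FALSE)
          planted <- planted[order(planted$start), , drop = FALSE]
        } else {
          planted <- NULL
        }
        # accept only if detectable sites are exactly the planted sites
        found <- scan_utrs(mirnas, stats::setNames(s, g))
        want <- if (is.null(planted)) 0L else nrow(planted)
        found <- `rownames<-`(
          found[order(found$start),
                c("gene", "mirna", "start", "end", "site_type")], NULL)
        if (nrow(found) == want &&
            (want == 0L || identical(found, `rownames<-`(planted, NULL)))) {
          utrs[[g]] <- s
          if (want > 0L) truth[[g]] <- planted
          break
        }
        if (try == 10000L) {
          stop_mircons("mircons_planting_error", "gene '", g,
                       "': could not realize a clean background")
        }
      }
    }
  })
  truth_sites <- if (length(truth)) {
    out <- do.call(rbind, truth); rownames(out) <- NULL; out
  } else {
    data.frame(gene = character(0), mirna = character(0),
               start = integer(0), end = integer(0),
               site_type = character(0), stringsAsFactors = FALSE)
  }
  structure(list(utr_sequences = utrs, mirnas = mirnas,
                 truth_sites = truth_sites, seed = seed),
            class = "utr_sim")
}

#' A predictor behaviour profile for the pseudo-predictor generator
#'
#' @param name predictor label.
#' @param sensitivity probability that a truth site is reported, in
#'   \[0, 1\].
#' @param false_calls_per_kb expected spurious calls per kb of UTR.
#' @param coordinate_jitter maximum nt by which reported boundaries are
#'   perturbed (0-3).
#' @return a `predictor_profile` list.
#' @export
predictor_profile <- function(name, sensitivity = 1,
                              false_calls_per_kb = 0,
                              coordinate_jitter = 0) {
  sensitivity <- check_fraction(sensitivity, "sensitivity")
  if (false_calls_per_kb < 0) {
    stop_mircons("mircons_parameter_error",
                 "false_calls_per_kb must be >= 0")
  }
  if (coordinate_jitter < 0 || coordinate_jitter > 3 ||
      coordinate_jitter != round(coordinate_jitter)) {
    stop_mircons("mircons_parameter_error",
                 "coordinate_jitter must be an integer in 0..3")
  }
  structure(list(name = name, sensitivity = sensitivity,
                 false_calls_per_kb = false_calls_per_kb,
                 coordinate_jitter = as.integer(coordinate_jitter)),
            class = "predictor_profile")
}

#' Simulate per-predictor site call tables from a UTR truth set
#'
#' Each profile reports every truth site independently with probability
#' `sensitivity`, perturbs reported boundaries by up to
#' `coordinate_jitter` nt, and adds Poisson spurious calls at
#' `false_calls_per_kb`. With perfect profiles (sensitivity 1, no false
#' calls, no jitter) the calls equal the truth sites exactly.
#'
#' @param truth a `utr_sim` object.
#' @param profiles list of [predictor_profile()]s (>= 1).
#' @param seed master integer seed.
#' @return named list of binding-site data frames, one per predictor.
#' @export
simulate_predictor_calls <- function(truth, profiles, seed = 1) {
  stopifnot(inherits(truth, "utr_sim"))
  if (length(profiles) < 1L) {
    stop_mircons("mircons_parameter_error", "need >= 1 predictor profile")
  }
  lens <- nchar(truth$utr_sequences)
  genes <- names(truth$utr_sequences)
  mir_ids <- names(truth$mirnas)
  out <- list()
  for (pr in profiles) {
    stopifnot(inherits(pr, "predictor_profile"))
    with_seed(substream_seed(seed, paste0("predictor:", pr$name)), {
      ts <- truth$truth_sites
      keep <- if (nrow(ts)) stats::runif(nrow(ts)) < pr$sensitivity else
        logical(0)
      calls <- ts[keep, , drop = FALSE]
      if (nrow(calls) && pr$coordinate_jitter > 0) {
        j <- pr$coordinate_jitter
        ds <- sample(seq(-j, j), nrow(calls), replace = TRUE)
        de <- sample(seq(-j, j), nrow(calls), replace = TRUE)
        calls$start <- pmax(0L, calls$start + ds)
        calls$end <- pmin(lens[calls$gene], calls$end + de)
        bad <- calls$end <= calls$start
        calls$end[bad] <- calls$start[bad] + 1L
        calls$site_type <- "other"         # jittered bounds lose the type
      }
      fc <- list()
      if (pr$false_calls_per_kb > 0 && length(mir_ids)) {
        for (g in genes) {
          nf <- stats::rpois(1L, pr$false_calls_per_kb * lens[[g]] / 1000)
          if (nf > 0) {
            w <- sample(6:8, nf, replace = TRUE)
            st <- vapply(w, function(wi)
              sample.int(lens[[g]] - wi + 1L, 1L) - 1L, 0L)
            fc[[g]] <- data.frame(gene = g,
                                  mirna = sample(mir_ids, nf, replace = TRUE),
                                  start = st, end = st + w,
                                  site_type = "other",
                                  stringsAsFactors = FALSE)
          }
        }
      }
      calls <- rbind(calls, do.call(rbind, fc))
    })
    if (is.null(calls) || nrow(calls) == 0L) {
      calls <- data.frame(gene = character(0), mirna = character(0),
                          start = integer(0), end = integer(0),
                          site_type = character(0), stringsAsFactors = FALSE)
    }
    calls$predictor <- rep(pr$name, nrow(calls))
    calls <- calls[order(calls$gene, calls$start, calls$mirna), , drop = FALSE]
    rownames(calls) <- NULL
    out[[pr$name]] <- calls
  }
  out
}

#' Simulate promoter sequences with planted CRE elements
#'
#' Backgrounds are rejection-sampled until free of accidental motif
#' occurrences, then the motif is planted at the requested per-gene counts
#' (>= 2 nt spacers) and the sequence re-checked, so the truth positions
#' are exactly the occurrences.
#'
#' @param n_genes number of promoters.
#' @param length promoter length in nt (default 1100: nominally -1000..+100
#'   around a TSS).
#' @param planted named integer vector gene id -> motif count; unnamed
#'   scalar recycles to all genes. Default gene ids `gene_001`, ...
#' @param motif motif to plant (default CRE octamer).
#' @param seed master integer seed.
#' @return class `promoter_sim`: `promoter_sequences` (named character),
#'   `truth_cre` (named list of 0-based start vectors), `motif`, `seed`.
#' @export
simulate_promoters <- function(n_genes, length = 1100, planted = 0,
                               motif = CRE_MOTIF, seed = 1) {
  n_genes <- check_positive_int(n_genes, "n_genes")
  length <- check_positive_int(length, "length")
  m <- normalize_dna(motif, allow_n = FALSE, what = "motif")
  gene_ids <- sprintf("gene_%03d", seq_len(n_genes))
  cnt <- stats::setNames(rep(0L, n_genes), gene_ids)
  if (is.null(names(planted))) {
    cnt[] <- as.integer(planted)
  } else {
    cnt[names(planted)] <- as.integer(planted)
  }
  if (any(nchar(m) * cnt >= length)) {
    stop_mircons("mircons_planting_error",
                 "planted motifs do not fit in the promoter length")
  }
  seqs <- character(0)
  truth <- stats::setNames(vector("list", n_genes), gene_ids)
  with_seed(substream_seed(seed, "promoter"), {
    for (g in gene_ids) {
      k <- cnt[[g]]
      for (try in seq_len(10000L)) {
        s <- random_dna(length)
        starts <- integer(0)
        if (k > 0) {
          starts <- place_blocks(rep(nchar(m), k), length)
          if (is.null(starts)) next
          chars <- strsplit(s, "", fixed = TRUE)[[1L]]
          for (st in starts) {
            chars[(st + 1L):(st + nchar(m))] <-
              strsplit(m, "", fixed = TRUE)[[1L]]
          }
          s <- paste(chars, collapse = "")
          starts <- sort(starts)
        }
        if (identical(match_starts(s, m), as.integer(starts))) {
          seqs[[g]] <- s
          truth[[g]] <- as.integer(starts)
          break
        }
        if (try == 10000L) {
          stop_mircons("mircons_planting_error", "gene '", g,
                       "': could not realize a clean promoter")
        }
      }
    }
  })
  structure(list(promoter_sequences = seqs, truth_cre = truth,
                 motif = m, seed = seed),
            class = "promoter_sim")
}

#' Simulate a phenotype coupled to the dCp of chosen genes
#'
#' `phenotype = slope * mean(dCp of coupled genes) + Normal noise`. On the
#' reversed dCp scale a positive slope therefore couples the phenotype to
#' LOWER expression of the coupled genes.
#'
#' @param dcp a `dcp_table` (see [compute_dcp()]).
#' @param coupled_genes genes driving the phenotype (must be in the table).
#' @param slope linear coupling coefficient.
#' @param noise_sd phenotype noise sd.
#' @param seed master integer seed.
#' @return named numeric vector, one value per sample.
#' @export
simulate_phenotype <- function(dcp, coupled_genes, slope = 1, noise_sd = 0,
                               seed = 1) {
  stopifnot(inherits(dcp, "dcp_table"))
  if (length(coupled_genes) == 0L) {
    stop_mircons("mircons_config_error", "coupled_genes must be non-empty")
  }
  missing <- setdiff(coupled_genes, colnames(dcp$dcp))
  if (length(missing)) {
    stop_mircons("mircons_config_error", "genes not in dCp table: ",
                 paste(missing, collapse = ", "))
  }
  if (noise_sd < 0) {
    stop_mircons("mircons_parameter_error", "noise_sd must be >= 0")
  }
  base <- rowMeans(dcp$dcp[, coupled_genes, drop = FALSE])
  with_seed(substream_seed(seed, "phenotype"), {
    noise <- stats::rnorm(length(base), 0, noise_sd)
  })
  stats::setNames(slope * base + noise, rownames(dcp$dcp))
}
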
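# End-to-end orchestration: synthetic inputs -> array DE -> consensus
# target prioritization -> qPCR statistics -> CRE promoter filtering,
# with a YAML run manifest (config hash, per-stage counts, output
# checksums, seed).

#' Default pipeline configuration
#'
#' Defaults mirror the study conditions: a 580-probe two-colour array
#' with 2 x 5 arrays, significance cut-off 1e-4 on Bonferroni-adjusted
#' p, top-100 ranking, full (k = 5) consensus over five predictors,
#' prioritization at >= 4 merged binding sites, and the palindromic CRE
#' octamer on 1100-nt promoters.
#'
#' @return a nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "mircons_run",
    stages = list(simulate = TRUE, de = TRUE, targets = TRUE,
                  qpcr = TRUE, cre = TRUE),
    simulate = list(n_probes = 580L, n_arrays = 10L, de_fraction = 0.06,
                    effect_log2 = 2, bg_mean = 100, bg_sd = 15,
                    signal_mean = 200, n_genes = 50L, utr_length = 500L,
                    n_promoters = 185L, n_cre_positive = 35L,
                    promoter_length = 1100L, n_per_group = 5L,
                    cp_noise_sd = 0.2),
    de = list(alpha = 1e-4, top_n = 100L, adjust = "bonferroni",
              spline_df = 5L, control_normalize = TRUE),
    consensus = list(k = 5L, min_sites = 4L),
    qpcr = list(reference_gene = "HPRT"),
    cre = list(motif = "TGACGTCA")
  )
}

# recursively check cfg against the default schema: unknown keys rejected
validate_config <- function(cfg, schema = default_config(), path = "") {
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown)) {
    stop_mircons("mircons_config_error", "unknown config key(s): ",
                 paste0(path, unknown, collapse = ", "))
  }
  for (key in names(cfg)) {
    if (is.list(schema[[key]])) {
      if (!is.list(cfg[[key]])) {
        stop_mircons("mircons_config_error", "config key ", path, key,
                     " must be a mapping")
      }
      validate_config(cfg[[key]], schema[[key]], paste0(path, key, "."))
    }
  }
  invisible(TRUE)
}

# overlay user values onto the defaults (validated first)
merge_config <- function(cfg = list()) {
  validate_config(cfg)
  merged <- default_config()
  overlay <- function(base, over) {
    for (key in names(over)) {
      base[[key]] <- if (is.list(base[[key]])) {
        overlay(base[[key]], over[[key]])
      } else {
        over[[key]]
      }
    }
    base
  }
  overlay(merged, cfg)
}

#' Load a pipeline configuration from YAML
#'
#' Unknown keys are rejected; omitted keys take the
#' [default_config()] values.
#'
#' @param path YAML file.
#' @return validated full configuration list.
#' @export
read_config <- function(path) {
  merge_config(yaml::read_yaml(path))
}

# write a file atomically (tmp + rename)
write_atomic <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

# default study miRNA panel for the bundled synthetic demo: sequences are
# synthetic; ids echo the miRNAs highlighted in murine AAI work. The set
# is rejection-sampled so that no miRNA's 6mer seed match occurs inside
# any planted 8mer site of another (or twice inside its own), keeping
# planted site counts exact for every master seed.
demo_mirnas <- function(seed) {
  ids <- c("miR-17-like", "miR-144-like", "miR-21-like", "miR-22-like",
           "miR-181a-like")
  with_seed(substream_seed(seed, "demo_mirnas"), {
    repeat {
      seqs <- vapply(ids, function(i)
        paste(sample(c("A", "C", "G", "U"), 22, replace = TRUE),
              collapse = ""), "")
      sites <- vapply(seqs, function(m) paste0(
        reverse_complement(substr(chartr("U", "T", m), 2L, 8L)), "A"), "")
      cores <- vapply(seqs, function(m)
        reverse_complement(substr(chartr("U", "T", m), 2L, 7L)), "")
      clean <- TRUE
      for (i in seq_along(ids)) {
        for (j in seq_along(ids)) {
          n_occ <- length(match_starts(sites[[j]], cores[[i]]))
          if (n_occ != as.integer(i == j)) { clean <- FALSE; break }
        }
        if (!clean) break
      }
      if (clean) break
    }
  })
  stats::setNames(seqs, ids)
}

# planted-site design for the demo: one Creb1-like gene with the
# 3+1+2+2 composition, four more genes at >= 4 sites, the rest sparse
demo_planted_counts <- function(n_genes, seed) {
  counts <- list(
    "Creb1-like" = c("miR-17-like" = 3L, "miR-144-like" = 1L,
                     "miR-22-like" = 2L, "miR-181a-like" = 2L))
  heavy <- sprintf("gene_%03d", 1:4)
  for (g in heavy) {
    counts[[g]] <- c("miR-17-like" = 2L, "miR-21-like" = 2L)
  }
  with_seed(substream_seed(seed, "demo_planting"), {
    sparse <- sprintf("gene_%03d", 5:min(n_genes, 14))
    for (g in sparse) {
      counts[[g]] <- stats::setNames(1L, sample(names(demo_mirnas(1)), 1L))
    }
  })
  counts
}

#' Run the full pipeline from a configuration
#'
#' Stages run in dependency order (simulate -> de, targets, qpcr, cre);
#' each stage writes its outputs before the next starts and any failure
#' aborts with the stage name, preserving prior outputs. The YAML
#' manifest records the config hash, input checksums, per-stage record
#' counts, wall time and seed; deterministic stages reproduce identical
#' checksums on rerun with the same config.
#'
#' @param config partial configuration list or path to a YAML file;
#'   omitted keys take [default_config()] values.
#' @return the manifest (invisibly written to `manifest.yaml` in
#'   `out_dir`).
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (is.character(config)) read_config(config) else
    merge_config(config)
  t0 <- Sys.time()
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed
  message("mircons pipeline: seed ", seed, ", out_dir ", cfg$out_dir)
  counts <- list()
  outputs <- character(0)
  path <- function(...) file.path(cfg$out_dir, ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_mircons("mircons_stage_error", "stage '", name, "' failed: ",
                   conditionMessage(e))
    })
  }

  # ---- simulate ----
  if (isTRUE(cfg$stages$simulate)) {
    stage("simulate", {
      sc <- cfg$simulate
      arr <- simulate_two_color_array(
        sc$n_probes, sc$n_arrays, de_fraction = sc$de_fraction,
        effect_log2 = sc$effect_log2, bg_mean = sc$bg_mean,
        bg_sd = sc$bg_sd, signal_mean = sc$signal_mean,
        seed = substream_seed(seed, "array"))
      write_atomic(function(p) write_intensities(arr, p,
        path("design.tsv")), path("intensities.tsv"))
      write_table(arr$truth, path("array_truth.tsv"))

      mirnas <- demo_mirnas(seed)
      utr <- simulate_utr_set(sc$n_genes, sc$utr_length, mirnas,
                              demo_planted_counts(sc$n_genes, seed),
                              seed = substream_seed(seed, "utr"))
      write_fasta(utr$utr_sequences, path("utrs.fasta"))
      write_fasta(chartr("T", "U", mirnas), path("mirnas.fasta"))
      write_bed(cbind(utr$truth_sites,
                      predictor = "truth", n_predictors = 1L),
                path("truth_sites.bed"))
      profiles <- lapply(paste0("predictor_", 1:5), predictor_profile)
      calls <- simulate_predictor_calls(utr, profiles,
                                        seed = substream_seed(seed, "calls"))
      all_calls <- do.call(rbind, c(calls, list(make.row.names = FALSE)))
      all_calls$score <- 0
      write_predictions(all_calls, path("predictions.tsv"))

      qg <- c(cfg$qpcr$reference_gene, names(mirnas))
      fc <- stats::setNames(c(0, 1, -1, 2, 0, 0), qg)
      cp <- simulate_cp_table(qg, n_per_group = sc$n_per_group,
                              true_log2fc = fc,
                              cp_noise_sd = sc$cp_noise_sd,
                              reference_gene = cfg$qpcr$reference_gene,
                              seed = substream_seed(seed, "cp"))
      write_cp_table(cp, path("cp.tsv"))

      planted <- stats::setNames(
        rep(c(1L, 0L), c(sc$n_cre_positive,
                         sc$n_promoters - sc$n_cre_positive)),
        sprintf("gene_%03d", seq_len(sc$n_promoters)))
      prom <- simulate_promoters(sc$n_promoters, sc$promoter_length,
                                 planted = planted, motif = cfg$cre$motif,
                                 seed = substream_seed(seed, "promoters"))
      write_fasta(prom$promoter_sequences, path("promoters.fasta"))
      writeLines(names(prom$promoter_sequences),
                 path("downregulated_genes.txt"))
      counts$simulate <- list(n_probes = nrow(arr$fg_r),
                               n_de_probes = sum(arr$truth$is_de),
                               n_utr_genes = length(utr$utr_sequences),
                               n_truth_sites = nrow(utr$truth_sites),
                               n_promoters = length(prom$promoter_sequences))
      outputs <- c(outputs, path(c("intensities.tsv", "design.tsv",
                                    "array_truth.tsv", "utrs.fasta",
                                    "mirnas.fasta", "truth_sites.bed",
                                    "predictions.tsv", "cp.tsv",
                                    "promoters.fasta",
                                    "downregulated_genes.txt")))
    })
  }

  # ---- de ----
  if (isTRUE(cfg$stages$de)) {
    stage("de", {
      sim <- read_intensities(path("intensities.tsv"), path("design.tsv"))
      de <- run_array_de(sim, alpha = cfg$de$alpha, top_n = cfg$de$top_n,
                         adjust = cfg$de$adjust,
                         spline_df = cfg$de$spline_df,
                         control_normalize = cfg$de$control_normalize)
      ranked <- de$calls$ranked
      write_table(ranked[, c("probe_id", "beta_hat", "t_mod", "p",
                             "p_adj", "rank")], path("de.tsv"))
      counts$de <- list(n_significant = nrow(de$calls$significant),
                         n_top = nrow(de$calls$top),
                         d0 = unname(attr(de$table, "d0")))
      outputs <- c(outputs, path("de.tsv"))
    })
  }

  # ---- targets ----
  if (isTRUE(cfg$stages$targets)) {
    stage("targets", {
      calls <- parse_predictions(path("predictions.tsv"))
      cons <- consensus_interactions(calls, k = cfg$consensus$k)
      prio <- prioritize_targets(cons, min_sites = cfg$consensus$min_sites)
      write_bed(cons$sites, path("consensus_sites.bed"))
      write_table(cons$pairs, path("consensus_pairs.tsv"))
      write_table(prio$genes, path("prioritized_genes.tsv"))
      bd <- as.data.frame(prio$breakdown)
      bd <- cbind(gene = rownames(prio$breakdown), bd)
      write_table(bd, path("site_breakdown.tsv"))
      counts$targets <- list(n_consensus_pairs = nrow(cons$pairs),
                              n_prioritized_genes = nrow(prio$genes))
      outputs <- c(outputs, path(c("consensus_sites.bed",
                                    "consensus_pairs.tsv",
                                    "prioritized_genes.tsv",
                                    "site_breakdown.tsv")))
    })
  }

  # ---- qpcr ----
  if (isTRUE(cfg$stages$qpcr)) {
    stage("qpcr", {
      cp <- read_cp_table(path("cp.tsv"), cfg$qpcr$reference_gene)
      tab <- qpcr_summary(cp)
      write_table(tab, path("qpcr.tsv"))
      counts$qpcr <- list(n_genes = nrow(tab))
      outputs <- c(outputs, path("qpcr.tsv"))
    })
  }

  # ---- cre ----
  if (isTRUE(cfg$stages$cre)) {
    stage("cre", {
      prom <- read_fasta(path("promoters.fasta"))
      down <- read_gene_list(path("downregulated_genes.txt"))
      hits <- scan_promoters(prom, motif = cfg$cre$motif)
      tab <- intersect_with_gene_set(hits, down)
      write_bed(hits, path("cre_hits.bed"))
      write_table(tab, path("cre_candidates.tsv"))
      counts$cre <- list(n_down = length(down),
                          n_candidates = sum(tab$is_candidate))
      outputs <- c(outputs, path(c("cre_hits.bed", "cre_candidates.tsv")))
    })
  }

  # ---- manifest ----
  cfg_file <- tempfile()
  yaml::write_yaml(cfg, cfg_file)
  manifest <- list(
    tool = paste0("mircons ",
                  as.character(utils::packageVersion("mircons"))),
    seed = seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    counts = counts,
    checksums = as.list(tools::md5sum(sort(unique(outputs)))),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  unlink(cfg_file)
  write_atomic(function(p) yaml::write_yaml(manifest, p),
               path("manifest.yaml"))
  invisible(manifest)
}
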
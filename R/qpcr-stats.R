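# Delta-delta-Ct quantification and nonparametric statistics for qPCR /
# low-density-array data.
#
# Scale convention: dCp = Cp_gene - Cp_reference per sample; HIGHER dCp
# means LOWER expression (reversed scale). ddCt = mean dCp(treated) -
# mean dCp(control); fold change = 2^-ddCt.

#' Construct a Cp table
#'
#' @param cp sample x gene numeric matrix of crossing-point values
#'   (cycles).
#' @param group_labels named character vector sample -> `treated` /
#'   `control`.
#' @param reference_gene reference gene id (must be a column of `cp`).
#' @return class `cp_table`.
#' @export
cp_table <- function(cp, group_labels, reference_gene) {
  cp <- as.matrix(cp)
  if (!reference_gene %in% colnames(cp)) {
    stop_mircons("mircons_config_error", "reference gene '",
                 reference_gene, "' not in the Cp table")
  }
  if (is.null(rownames(cp))) {
    rownames(cp) <- sprintf("sample_%02d", seq_len(nrow(cp)))
  }
  missing <- setdiff(rownames(cp), names(group_labels))
  if (length(missing)) {
    stop_mircons("mircons_config_error", "samples without a group: ",
                 paste(missing, collapse = ", "))
  }
  bad <- !group_labels[rownames(cp)] %in% c("treated", "control")
  if (any(bad)) {
    stop_mircons("mircons_config_error",
                 "group labels must be 'treated' or 'control'")
  }
  structure(list(cp = cp, group_labels = group_labels[rownames(cp)],
                 reference_gene = reference_gene),
            class = "cp_table")
}

#' Reference-normalize a Cp table to dCp values
#'
#' `dCp = Cp_gene - Cp_reference` per sample; missing Cp propagates as
#' missing, but a missing reference in any sample is an error (nothing on
#' that sample could be normalized).
#'
#' @param cp a [cp_table()].
#' @return class `dcp_table`: `dcp` matrix, `group_labels`,
#'   `reference_gene`, `scale_note`.
#' @export
compute_dcp <- function(cp) {
  stopifnot(inherits(cp, "cp_table"))
  ref <- cp$cp[, cp$reference_gene]
  bad <- rownames(cp$cp)[is.na(ref)]
  if (length(bad)) {
    stop_mircons("mircons_config_error",
                 "reference gene missing in sample(s): ",
                 paste(bad, collapse = ", "))
  }
  structure(list(dcp = cp$cp - ref, group_labels = cp$group_labels,
                 reference_gene = cp$reference_gene,
                 scale_note = "higher dCp means lower expression"),
            class = "dcp_table")
}

#' Delta-delta-Ct fold change for one gene
#'
#' @param dcp a `dcp_table`.
#' @param gene gene id.
#' @param summary group summary: arithmetic `"mean"` (standard
#'   delta-delta-Ct) or `"median"`.
#' @return list: `ddct`, `fold_change` (`2^-ddct`), `log2_fold_change`
#'   (`-ddct`).
#' @export
ddct_fold_change <- function(dcp, gene, summary = c("mean", "median")) {
  stopifnot(inherits(dcp, "dcp_table"))
  summary <- match.arg(summary)
  if (!gene %in% colnames(dcp$dcp)) {
    stop_mircons("mircons_config_error", "gene '", gene,
                 "' not in the dCp table")
  }
  v <- dcp$dcp[, gene]
  g <- dcp$group_labels
  tr <- v[g == "treated"]; ct <- v[g == "control"]
  tr <- tr[!is.na(tr)]; ct <- ct[!is.na(ct)]
  if (!length(tr) || !length(ct)) {
    stop_mircons("mircons_config_error", "gene '", gene,
                 "': empty group after removing missing values")
  }
  f <- if (summary == "mean") mean else stats::median
  ddct <- f(tr) - f(ct)
  list(ddct = ddct, fold_change = 2^(-ddct), log2_fold_change = -ddct)
}

#' Mann-Whitney U test with exact small-sample enumeration
#'
#' For `n + m <= 12` the p-value is exact: all `choose(n + m, n)` group
#' assignments are enumerated on the mid-ranks of the pooled data (ties
#' handled by construction); the two-sided p uses the symmetry of U about
#' `n * m / 2`. Larger samples use the normal approximation with tie and
#' continuity corrections.
#'
#' @param x,y numeric vectors (non-empty).
#' @param alternative `"two_sided"`, `"less"` or `"greater"` (of `x`
#'   relative to `y`).
#' @return list: `U` (statistic for `x`), `p`, `exact` (logical).
#' @export
mann_whitney <- function(x, y,
                         alternative = c("two_sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n <- length(x); m <- length(y)
  if (n < 1L || m < 1L) {
    stop_mircons("mircons_parameter_error", "both groups must be non-empty")
  }
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  eps <- 1e-9
  if (n + m <= 12L) {
    idx <- utils::combn(n + m, n)
    us <- colSums(matrix(r[idx], nrow = n)) - n * (n + 1) / 2
    p <- switch(alternative,
      two_sided = mean(abs(us - n * m / 2) >= abs(u_obs - n * m / 2) - eps),
      less = mean(us <= u_obs + eps),
      greater = mean(us >= u_obs - eps))
    return(list(U = u_obs, p = p, exact = TRUE))
  }
  N <- n + m
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n * m / 12 * ((N + 1) - tie_term)
  mu <- n * m / 2
  p <- switch(alternative,
    two_sided = min(1, 2 * stats::pnorm(
      -max(abs(u_obs - mu) - 0.5, 0) / sqrt(sigma2))),
    less = stats::pnorm((u_obs + 0.5 - mu) / sqrt(sigma2)),
    greater = 1 - stats::pnorm((u_obs - 0.5 - mu) / sqrt(sigma2)))
  list(U = u_obs, p = p, exact = FALSE)
}

# all permutations of 1..n as an n! x n matrix (n <= 8)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out[row:(row + nrow(sub) - 1L), ] <-
      cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
    row <- row + nrow(sub)
  }
  out
}

#' Spearman rank correlation with exact small-sample permutation p
#'
#' rho is the Pearson correlation of mid-ranks (average ranks for ties).
#' For `n <= 8` the two-sided p-value is exact by full enumeration of all
#' `n!` permutations; larger samples use the t approximation with
#' `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors (pairwise-complete, >= 3 pairs).
#' @return list: `rho`, `p`, `n`, `exact`.
#' @export
spearman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) {
    stop_mircons("mircons_parameter_error", "need >= 3 complete pairs")
  }
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop_mircons("mircons_estimation_error",
                 "rho undefined for a constant vector")
  }
  rho <- stats::cor(rx, ry)
  eps <- 1e-12
  if (n <= 8L) {
    perms <- all_perms(n)
    rhos <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - eps)
    return(list(rho = rho, p = p, n = n, exact = TRUE))
  }
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(rho = rho, p = p, n = n, exact = FALSE)
}

#' Cross-platform concordance of two per-id value sets
#'
#' Inner-joins the two named vectors on shared ids with both values
#' present and reports the Spearman correlation on the matched set;
#' exclusions are recorded with a reason (`absent_in_a` / `absent_in_b`
#' for ids missing from a platform, `below_detection_a` / `_b` for `NA`
#' measurements).
#'
#' @param a,b named numeric vectors (id -> value).
#' @return list: `rho`, `p`, `n_matched`, `matched_ids`, `excluded`
#'   (data frame `id`, `reason`).
#' @export
cross_platform_concordance <- function(a, b) {
  ids <- union(names(a), names(b))
  reason <- character(0); excl <- character(0)
  note <- function(id, why) {
    excl <<- c(excl, id); reason <<- c(reason, why)
  }
  matched <- character(0)
  for (id in ids) {
    if (!id %in% names(a)) note(id, "absent_in_a")
    else if (!id %in% names(b)) note(id, "absent_in_b")
    else if (is.na(a[[id]])) note(id, "below_detection_a")
    else if (is.na(b[[id]])) note(id, "below_detection_b")
    else matched <- c(matched, id)
  }
  excluded <- data.frame(id = excl, reason = reason,
                         stringsAsFactors = FALSE)
  if (length(matched) < 3L) {
    stop_mircons("mircons_estimation_error",
                 "concordance undefined: fewer than 3 matched ids")
  }
  sp <- spearman(a[matched], b[matched])
  list(rho = sp$rho, p = sp$p, n_matched = length(matched),
       matched_ids = matched, excluded = excluded)
}

#' Correlate a gene's dCp values with a phenotype
#'
#' Spearman correlation of per-sample dCp against a phenotype (e.g. BAL
#' total cell counts, airway resistance). Because dCp is a reversed
#' scale, a POSITIVE rho on dCp means a NEGATIVE association with
#' expression; the output records the convention.
#'
#' @param dcp a `dcp_table`.
#' @param phenotype named numeric vector (sample -> value).
#' @param gene gene id.
#' @return list: `rho`, `p`, `n`, `scale_note`.
#' @export
correlate_phenotype <- function(dcp, phenotype, gene) {
  stopifnot(inherits(dcp, "dcp_table"))
  if (!gene %in% colnames(dcp$dcp)) {
    stop_mircons("mircons_config_error", "gene '", gene,
                 "' not in the dCp table")
  }
  shared <- intersect(rownames(dcp$dcp), names(phenotype))
  if (length(shared) < 3L) {
    stop_mircons("mircons_parameter_error",
                 "need >= 3 overlapping samples")
  }
  sp <- spearman(dcp$dcp[shared, gene], phenotype[shared])
  list(rho = sp$rho, p = sp$p, n = sp$n,
       scale_note = paste("dCp is a reversed scale: positive rho on dCp",
                          "means negative association with expression"))
}

#' Per-gene delta-delta-Ct and Mann-Whitney summary table
#'
#' @param cp a [cp_table()].
#' @return data frame: `gene_id`, `ddct`, `fold_change`,
#'   `log2_fold_change`, `U`, `p` (reference gene excluded).
#' @export
qpcr_summary <- function(cp) {
  stopifnot(inherits(cp, "cp_table"))
  dcp <- compute_dcp(cp)
  genes <- setdiff(colnames(cp$cp), cp$reference_gene)
  rows <- lapply(genes, function(g) {
    fc <- ddct_fold_change(dcp, g)
    v <- dcp$dcp[, g]; gl <- dcp$group_labels
    mw <- mann_whitney(v[gl == "treated"], v[gl == "control"])
    data.frame(gene_id = g, ddct = fc$ddct, fold_change = fc$fold_change,
               log2_fold_change = fc$log2_fold_change, U = mw$U, p = mw$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
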
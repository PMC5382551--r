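# Two-colour array differential expression.
#
# Chain: normexp background correction (observed = Normal background +
# Exponential signal; corrected value is E[signal | observed]) -> M/A
# computation -> optional control-probe centring -> robust-spline
# within-array normalization of M on A -> MAD scaling between arrays ->
# per-probe OLS -> empirical-Bayes variance moderation (digamma/trigamma
# moment matching on log s^2) -> multiple-testing adjustment -> ranked
# calls.

#' Fit normexp parameters to observed intensities
#'
#' Maximum likelihood for the Normal(mu, sigma) + Exponential(mean alpha)
#' convolution, started from the method of moments (third central moment
#' identifies alpha) and refined numerically.
#'
#' @param observed vector of positive intensities (>= 50 values).
#' @return list `mu`, `sigma`, `alpha` (class `normexp_params`).
#' @export
estimate_normexp_params <- function(observed) {
  x <- as.numeric(observed)
  if (length(x) < 50L || any(!is.finite(x)) || any(x <= 0)) {
    stop_mircons("mircons_parameter_error",
                 "need >= 50 finite positive observations")
  }
  if (stats::sd(x) == 0) {
    stop_mircons("mircons_estimation_error",
                 "degenerate data: zero variance")
  }
  m1 <- mean(x); v <- stats::var(x)
  m3 <- mean((x - m1)^3)
  alpha0 <- max((max(m3, 1e-12) / 2)^(1 / 3), sqrt(v) / 10)
  sigma0 <- sqrt(max(v - alpha0^2, v / 100))
  mu0 <- m1 - alpha0

  nll <- function(par) {
    mu <- par[1L]; sigma <- exp(par[2L]); alpha <- exp(par[3L])
    # log density of N(mu, sigma) + Exp(alpha), computed stably
    z <- (x - mu - sigma^2 / alpha) / sigma
    ll <- -log(alpha) + (mu - x) / alpha + sigma^2 / (2 * alpha^2) +
      stats::pnorm(z, log.p = TRUE)
    if (any(!is.finite(ll))) return(1e10)
    -sum(ll)
  }
  start <- c(mu0, log(sigma0), log(alpha0))
  fit <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  fit <- stats::optim(fit$par, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  structure(list(mu = fit$par[1L], sigma = exp(fit$par[2L]),
                 alpha = exp(fit$par[3L])),
            class = "normexp_params")
}

#' Normexp background correction of a single intensity
#'
#' Returns `E[S | X = x] = mu_s + sigma * phi(mu_s/sigma) / Phi(mu_s/sigma)`
#' with `mu_s = x - mu - sigma^2/alpha`. The inverse-Mills ratio is
#' computed on the log scale so the result is strictly positive and
#' strictly increasing in `x` even far below the background mean.
#'
#' @param x observed intensity (vectorized).
#' @param params a `normexp_params` list (`mu`, `sigma`, `alpha`).
#' @return corrected intensity, strictly positive.
#' @export
normexp_transform <- function(x, params) {
  mu <- params$mu; sigma <- params$sigma; alpha <- params$alpha
  if (!is.finite(sigma) || sigma <= 0 || !is.finite(alpha) || alpha <= 0) {
    stop_mircons("mircons_parameter_error", "invalid normexp parameters")
  }
  mu_s <- x - mu - sigma^2 / alpha
  z <- mu_s / sigma
  # phi(z)/Phi(z), stable for z << 0 via log-scale computation
  mills <- exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE))
  out <- mu_s + sigma * mills
  # far left tail: E[S|X] -> sigma * (phi/Phi)^-1 asymptote ~ -sigma^2/mu_s
  tiny <- !is.finite(out) | out <= 0
  out[tiny] <- -sigma^2 / mu_s[tiny]
  out
}

#' Compute M/A profiles from corrected channel intensities
#'
#' @param r,g matrices (probe x array) of corrected red/green intensities,
#'   strictly positive.
#' @return list of matrices `M` (log2 R/G) and `A` (mean log2 intensity).
#' @export
compute_ma <- function(r, g) {
  stopifnot(all(r > 0), all(g > 0))
  list(M = log2(r) - log2(g), A = (log2(r) + log2(g)) / 2)
}

#' Robust-spline within-array normalization of M on A
#'
#' Fits a robust (Huber-weighted) cubic B-spline trend of M on A with
#' knots at equally spaced A-quantiles and subtracts it. With fewer than
#' `5 * spline_df` probes the fit falls back to median-centring with a
#' warning.
#'
#' @param M,A numeric vectors (one array).
#' @param spline_df spline degrees of freedom (default 5).
#' @return normalized M.
#' @export
normalize_within_array <- function(M, A, spline_df = 5) {
  spline_df <- check_positive_int(spline_df, "spline_df")
  ok <- is.finite(M) & is.finite(A)
  if (sum(ok) < 5L * spline_df) {
    warning("too few probes for spline normalization; median-centring")
    return(M - stats::median(M[ok]))
  }
  knots <- stats::quantile(A[ok], probs = seq_len(spline_df - 1) / spline_df)
  basis <- splines::bs(A, degree = 3L, knots = knots,
                       Boundary.knots = range(A[ok]))
  x <- cbind(1, basis)
  fit <- MASS::rlm(x[ok, , drop = FALSE], M[ok],
                   psi = MASS::psi.huber, maxit = 200)
  trend <- drop(x %*% stats::coef(fit))
  M - trend
}

#' Scale M values between arrays to a common spread
#'
#' Divides each array by its median absolute deviation and rescales to the
#' geometric mean of the per-array MADs, so all arrays end with identical
#' MAD.
#'
#' @param M probe x array matrix of normalized log-ratios (>= 2 arrays).
#' @return rescaled matrix.
#' @export
scale_between_arrays <- function(M) {
  if (ncol(M) < 2L) {
    stop_mircons("mircons_parameter_error", "need >= 2 arrays")
  }
  mads <- apply(M, 2L, stats::mad, na.rm = TRUE)
  zero <- which(mads == 0)
  if (length(zero)) {
    nm <- colnames(M)[zero]
    if (is.null(nm)) nm <- as.character(zero)
    stop_mircons("mircons_scaling_error", "zero MAD in array(s): ",
                 paste(nm, collapse = ", "))
  }
  target <- geo_mean(mads)
  sweep(M, 2L, mads / target, "/")
}

#' Per-probe ordinary least squares against a design matrix
#'
#' @param M probe x array matrix.
#' @param design array x coefficient design matrix (full rank, fewer
#'   coefficients than arrays).
#' @return list: `coefficients` (probe x coefficient), `stdev_unscaled`
#'   (sqrt of the diagonal of `(X'X)^-1`, per coefficient), `s2`
#'   (residual variances), `df_resid`.
#' @export
fit_linear_model <- function(M, design) {
  design <- as.matrix(design)
  n <- ncol(M)
  if (nrow(design) != n) {
    stop_mircons("mircons_design_error",
                 "design rows must equal the number of arrays")
  }
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    stop_mircons("mircons_design_error", "design matrix is rank deficient")
  }
  if (n < ncol(design) + 1L) {
    stop_mircons("mircons_design_error",
                 "need at least one residual degree of freedom")
  }
  fit <- stats::lm.fit(design, t(M))
  beta <- t(fit$coefficients)
  df <- n - qrd$rank
  s2 <- colSums(as.matrix(fit$residuals)^2) / df
  xtxi <- chol2inv(qr.R(qrd))
  su <- sqrt(diag(xtxi))
  names(su) <- colnames(design)
  colnames(beta) <- colnames(design)
  list(coefficients = beta, stdev_unscaled = su, s2 = as.numeric(s2),
       df_resid = rep(df, nrow(M)))
}

# solve trigamma(y) = x by Newton iteration on 1/y (limma-style schedule)
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in seq_len(50L)) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2L)
      y <- y + dif
      if (abs(dif / y) < 1e-10) break
    }
    y
  }, 0)
}

#' Empirical-Bayes moderation of per-probe variances
#'
#' Models `s2_g ~ s0^2 * F(d_g, d0)` and estimates `(d0, s0^2)` by
#' matching the mean and variance of `log s2` to the scaled-F theory
#' (digamma/trigamma inversion). Posterior variances are
#' `s2_post = (d0 * s0^2 + d_g * s2_g) / (d0 + d_g)`; the moderated t of
#' a downstream contrast uses `d0 + d_g` degrees of freedom. When the
#' dispersion of `log s2` does not exceed its sampling expectation, `d0`
#' is reported as `Inf` (full pooling) with a warning.
#'
#' @param s2 per-probe residual variances (>= 10 positive values).
#' @param df_resid per-probe residual degrees of freedom (scalar or
#'   vector).
#' @param d0 optionally force the prior degrees of freedom (`0` gives the
#'   ordinary, unmoderated statistic).
#' @return list: `d0`, `s0_2`, `s2_post`, `df_total`.
#' @export
moderate_variances <- function(s2, df_resid, d0 = NULL) {
  s2 <- as.numeric(s2)
  df <- rep_len(as.numeric(df_resid), length(s2))
  pos <- s2 > 0 & is.finite(s2) & df > 0
  if (sum(pos) < 10L) {
    stop_mircons("mircons_estimation_error",
                 "need >= 10 probes with positive variance")
  }
  if (!is.null(d0)) {
    if (d0 == 0) {
      return(list(d0 = 0, s0_2 = NA_real_, s2_post = s2, df_total = df))
    }
    forced <- TRUE
  } else {
    forced <- FALSE
  }
  e <- log(s2[pos])
  dg <- df[pos]
  # centre by the log-chisq sampling mean so the residual dispersion is
  # attributable to the prior
  e_adj <- e - digamma(dg / 2) + log(dg / 2)
  if (!forced) {
    ev <- stats::var(e_adj) * (length(e_adj) - 1) / length(e_adj)
    excess <- ev - mean(trigamma(dg / 2))
    if (excess <= 0) {
      warning("no excess dispersion in log s2; reporting d0 = Inf ",
              "(fully pooled)")
      d0 <- Inf
      if (ev == 0) {
        # literally constant variances: they ARE the prior, no
        # log-chisq bias adjustment applies
        return(list(d0 = Inf, s0_2 = s2[pos][1L],
                    s2_post = rep(s2[pos][1L], length(s2)),
                    df_total = rep(Inf, length(s2))))
      }
    } else {
      d0 <- 2 * trigamma_inverse(excess)
    }
  }
  if (is.finite(d0)) {
    s0_2 <- exp(mean(e_adj) + digamma(d0 / 2) - log(d0 / 2))
    s2_post <- (d0 * s0_2 + df * s2) / (d0 + df)
  } else {
    s0_2 <- exp(mean(e_adj))
    s2_post <- rep(s0_2, length(s2))
  }
  list(d0 = d0, s0_2 = s0_2, s2_post = s2_post, df_total = d0 + df)
}

#' Adjust p-values for multiple testing
#'
#' Bonferroni (`min(1, m * p)`) or Benjamini-Hochberg step-up.
#'
#' @param p vector of p-values in \[0, 1\].
#' @param method `"bonferroni"` or `"bh"`.
#' @return adjusted p-values, same order as input.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop_mircons("mircons_validation_error", "p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}

#' Moderated-t differential expression table
#'
#' Combines [fit_linear_model()] and [moderate_variances()] for one
#' coefficient and attaches two-sided p-values and adjusted p-values.
#'
#' @param fit result of [fit_linear_model()].
#' @param coef coefficient name or index to test.
#' @param adjust adjustment method for [adjust_pvalues()].
#' @param d0 optional forced prior df (see [moderate_variances()]).
#' @param probe_ids probe identifiers (default from the fit).
#' @return class `de_result`: data frame `probe_id`, `beta_hat`, `s2`,
#'   `df_resid`, `t_mod`, `p`, `p_adj` with attributes `d0`, `s0_2`,
#'   `s2_post`.
#' @export
moderated_t_table <- function(fit, coef = ncol(fit$coefficients),
                              adjust = c("bonferroni", "bh"), d0 = NULL,
                              probe_ids = rownames(fit$coefficients)) {
  adjust <- match.arg(adjust)
  beta <- fit$coefficients[, coef]
  su <- fit$stdev_unscaled[[coef]]
  mod <- moderate_variances(fit$s2, fit$df_resid, d0 = d0)
  df_t <- if (mod$d0 == 0) fit$df_resid else mod$df_total
  t_mod <- beta / (su * sqrt(mod$s2_post))
  p <- 2 * stats::pt(-abs(t_mod), df = df_t)
  if (is.null(probe_ids)) probe_ids <- sprintf("probe_%05d", seq_along(beta))
  res <- data.frame(probe_id = probe_ids, beta_hat = as.numeric(beta),
                    s2 = fit$s2, df_resid = fit$df_resid,
                    t_mod = as.numeric(t_mod), p = as.numeric(p),
                    p_adj = adjust_pvalues(as.numeric(p), adjust),
                    stringsAsFactors = FALSE)
  attr(res, "d0") <- mod$d0
  attr(res, "s0_2") <- mod$s0_2
  attr(res, "s2_post") <- mod$s2_post
  class(res) <- c("de_result", "data.frame")
  res
}

#' Call differential miRNAs and rank the list
#'
#' @param results a `de_result` table.
#' @param alpha adjusted-p cut-off (study default 1e-4).
#' @param top_n size of the ranked head list (study default 100).
#' @param use_adjusted apply `alpha` to adjusted (default) or raw p.
#' @return list: `significant` (rows passing the cut-off), `top` (the
#'   `top_n` best-ranked rows), `ranked` (all rows, ranked by ascending
#'   adjusted p, ties by |beta_hat| descending then probe id).
#' @export
call_de <- function(results, alpha = 1e-4, top_n = 100,
                    use_adjusted = TRUE) {
  o <- order(results$p_adj, -abs(results$beta_hat), results$probe_id)
  ranked <- results[o, , drop = FALSE]
  ranked$rank <- seq_len(nrow(ranked))
  rownames(ranked) <- NULL
  pcol <- if (use_adjusted) ranked$p_adj else ranked$p
  list(significant = ranked[pcol < alpha, , drop = FALSE],
       top = utils::head(ranked, top_n),
       ranked = ranked)
}

#' Run the full two-colour array DE chain on a simulated or file-backed
#' experiment
#'
#' Per array and channel: normexp parameters are estimated from the
#' foreground intensities and the corrected signal is `E[S|X]`; M/A are
#' computed, optionally centred on the control probes (the "RNU6B" role),
#' spline-normalized within arrays, MAD-scaled between arrays, and tested
#' with the moderated t for the treatment coefficient.
#'
#' @param sim an `array_sim` object (or a list with the same fields).
#' @param alpha,top_n,adjust see [call_de()] / [moderated_t_table()].
#' @param spline_df within-array spline df.
#' @param control_normalize centre M on the control probes first.
#' @return list: `table` (`de_result`), `calls` (from [call_de()]), `M`
#'   (final normalized matrix), `normexp` (per array/channel parameter
#'   fits).
#' @export
run_array_de <- function(sim, alpha = 1e-4, top_n = 100,
                         adjust = "bonferroni", spline_df = 5,
                         control_normalize = TRUE) {
  n_arr <- ncol(sim$fg_r)
  corr_r <- sim$fg_r; corr_g <- sim$fg_g
  normexp <- list()
  for (j in seq_len(n_arr)) {
    pr <- estimate_normexp_params(sim$fg_r[, j])
    pg <- estimate_normexp_params(sim$fg_g[, j])
    corr_r[, j] <- normexp_transform(sim$fg_r[, j], pr)
    corr_g[, j] <- normexp_transform(sim$fg_g[, j], pg)
    normexp[[colnames(sim$fg_r)[j]]] <- list(R = pr, G = pg)
  }
  ma <- compute_ma(corr_r, corr_g)
  M <- ma$M; A <- ma$A
  ctrl <- sim$probe_ids %in% sim$control_probe_ids
  if (control_normalize && any(ctrl)) {
    M <- sweep(M, 2L, colMeans(M[ctrl, , drop = FALSE]), "-")
  }
  for (j in seq_len(n_arr)) {
    M[, j] <- normalize_within_array(M[, j], A[, j], spline_df = spline_df)
  }
  M <- scale_between_arrays(M)
  design <- cbind(intercept = 1,
                  treated = as.numeric(sim$group_labels == "treated"))
  fit <- fit_linear_model(M, design)
  tab <- moderated_t_table(fit, coef = "treated", adjust = adjust,
                           probe_ids = sim$probe_ids)
  list(table = tab, calls = call_de(tab, alpha = alpha, top_n = top_n),
       M = M, normexp = normexp)
}
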
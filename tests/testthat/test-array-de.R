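# Normexp background correction, normalization, per-probe OLS,
# empirical-Bayes variance moderation and multiple-testing adjustment.

test_that("normexp transform matches its closed form, limits and
           quadrature oracle", {
  # sigma -> 0 limit: corrected = x - mu
  p0 <- list(mu = 10, sigma = 1e-6, alpha = 1e6)
  expect_equal(normexp_transform(110, p0), 100, tolerance = 1e-4)
  # positivity even far below the background mean
  p <- list(mu = 100, sigma = 15, alpha = 200)
  expect_gt(normexp_transform(5, p), 0)
  expect_gt(normexp_transform(-500, p), 0)
  # quadrature oracle over the conditional density
  for (x in c(20, 60, 90, 100, 110, 120, 200, 400)) {
    expect_equal(normexp_transform(x, p), quad_normexp(x, 100, 15, 200),
                 tolerance = 1e-6)
  }
  # agreement with the reference implementation
  if (requireNamespace("limma", quietly = TRUE)) {
    xs <- c(5, 50, 100, 150, 300)
    ref <- limma::normexp.signal(c(100, log(15), log(200)), xs)
    expect_equal(normexp_transform(xs, p), ref, tolerance = 1e-8)
  }
})

test_that("normexp transform is strictly positive and monotone on a grid", {
  p <- list(mu = 100, sigma = 15, alpha = 200)
  grid <- seq(100 - 10 * 15, 100 + 20 * 15, length.out = 10000)
  v <- normexp_transform(grid, p)
  expect_true(all(v > 0))
  expect_true(all(diff(v) > 0))
})

test_that("normexp parameters are recovered from simulated data", {
  set.seed(71)
  x <- rnorm(10000, 100, 15) + rexp(10000, 1 / 200)
  est <- estimate_normexp_params(x)
  expect_lt(abs(est$mu - 100) / 100, 0.10)
  expect_lt(abs(est$sigma - 15) / 15, 0.10)
  expect_lt(abs(est$alpha - 200) / 200, 0.10)
  # boundary: pure exponential data drives sigma to a sliver of alpha
  y <- 50 + rexp(5000, 1 / 300)
  est2 <- estimate_normexp_params(y)
  expect_lt(est2$sigma, 0.1 * est2$alpha)
  expect_error(estimate_normexp_params(rep(5, 100)),
               class = "mircons_estimation_error")
  expect_error(estimate_normexp_params(c(-1, rexp(99) + 1)),
               class = "mircons_parameter_error")
})

test_that("robust spline normalization removes a planted trend and
           resists outliers", {
  # exact zero input is returned unchanged
  set.seed(72)
  A0 <- rnorm(400, 10, 2)
  expect_equal(normalize_within_array(rep(0, 400), A0), rep(0, 400),
               tolerance = 1e-8)
  # planted smooth trend: residual trend RMS < 10% of the trend RMS
  A <- sort(runif(600, 6, 14))
  f <- 0.5 * sin((A - 6) / 8 * 2 * pi) + 0.1 * (A - 10)
  M <- f + rnorm(600, 0, 0.05)
  Mn <- normalize_within_array(M, A)
  resid_trend <- Mn - (M - f)    # what is left of f after normalization
  expect_lt(sqrt(mean(resid_trend^2)), 0.1 * sqrt(mean(f^2)))
  # 10% outliers at M + 8 barely move the trend
  out_idx <- sample(600, 60)
  M_out <- M; M_out[out_idx] <- M_out[out_idx] + 8
  Mn_out <- normalize_within_array(M_out, A)
  expect_lt(max(abs((M_out - Mn_out) - (M - Mn))[-out_idx]), 0.1)
  # fallback with a warning when probes are too few
  expect_warning(normalize_within_array(rnorm(10), rnorm(10)),
                 "median-centring")
})

test_that("between-array scaling equalizes MADs exactly", {
  set.seed(73)
  M <- cbind(a = rnorm(300), b = 3 * rnorm(300), c = 0.5 * rnorm(300))
  S <- scale_between_arrays(M)
  mads <- apply(S, 2, mad)
  expect_lt(max(mads) / min(mads) - 1, 1e-12)
  # identical-spread arrays come back unchanged
  M2 <- cbind(M[, 1], M[, 1][sample(300)])
  expect_equal(scale_between_arrays(M2), M2)
  bad <- cbind(x = rnorm(50), y = rep(1, 50))
  expect_error(scale_between_arrays(bad), "y",
               class = "mircons_scaling_error")
  expect_error(scale_between_arrays(M[, 1, drop = FALSE]),
               class = "mircons_parameter_error")
})

test_that("per-probe OLS matches the normal-equations oracle", {
  # noise-free two-group design recovers the difference exactly
  M <- rbind(c(1, 1, 1, 0, 0, 0))
  design <- cbind(intercept = 1, treated = rep(c(1, 0), each = 3))
  fit <- fit_linear_model(M, design)
  expect_equal(unname(fit$coefficients[1, "treated"]), 1)
  expect_equal(fit$s2, 0)
  expect_equal(fit$df_resid, 4L, ignore_attr = TRUE)
  # intercept-only design returns row means
  fit0 <- fit_linear_model(M, matrix(1, 6, 1))
  expect_equal(unname(fit0$coefficients[, 1]), mean(M))
  # random case against solve(X'X) X'y per probe
  set.seed(74)
  M8 <- matrix(rnorm(50 * 8), 50, 8)
  X <- cbind(1, rep(c(1, 0), each = 4), rnorm(8))
  f <- fit_linear_model(M8, X)
  for (i in c(1, 17, 50)) {
    beta <- solve(crossprod(X), crossprod(X, M8[i, ]))
    expect_equal(unname(f$coefficients[i, ]), drop(beta),
                 tolerance = 1e-10)
    r <- M8[i, ] - X %*% beta
    expect_equal(f$s2[i], sum(r^2) / (8 - 3), tolerance = 1e-10)
  }
  expect_error(fit_linear_model(M8, cbind(1, 1:8, 2 * (1:8))),
               class = "mircons_design_error")
})

test_that("variance moderation recovers the prior and shrinks towards it", {
  set.seed(75)
  d0 <- 4; s0 <- 0.05; d <- 8; n <- 5000
  sigma2 <- d0 * s0 / rchisq(n, d0)        # scaled inverse chi-square prior
  s2 <- sigma2 * rchisq(n, d) / d
  mod <- moderate_variances(s2, d)
  expect_gt(mod$d0, 2.8); expect_lt(mod$d0, 5.6)
  expect_lt(abs(mod$s0_2 - s0) / s0, 0.15)
  # posterior lies between the observed and prior variance
  expect_true(all(mod$s2_post >= pmin(s2, mod$s0_2) - 1e-12))
  expect_true(all(mod$s2_post <= pmax(s2, mod$s0_2) + 1e-12))
  expect_true(all(abs(mod$s2_post - mod$s0_2) <= abs(s2 - mod$s0_2) + 1e-12))
  # agreement with the reference empirical-Bayes implementation
  if (requireNamespace("limma", quietly = TRUE)) {
    ref <- limma::squeezeVar(s2, df = d)
    expect_equal(mod$d0, ref$df.prior, tolerance = 0.02)
    expect_equal(mod$s0_2, ref$var.prior, tolerance = 0.02)
    expect_equal(mod$s2_post, ref$var.post, tolerance = 0.01)
  }
  # identical variances: d0 = Inf with full pooling
  expect_warning(flat <- moderate_variances(rep(0.3, 100), 6), "Inf")
  expect_equal(flat$d0, Inf)
  expect_equal(flat$s2_post, rep(0.3, 100))
  expect_error(moderate_variances(rep(0, 20), 6),
               class = "mircons_estimation_error")
})

test_that("d0 = 0 reproduces the ordinary t exactly", {
  set.seed(76)
  M <- matrix(rnorm(200 * 8), 200, 8)
  design <- cbind(1, rep(c(1, 0), each = 4))
  colnames(design) <- c("intercept", "treated")
  fit <- fit_linear_model(M, design)
  tab <- moderated_t_table(fit, coef = "treated", d0 = 0)
  for (i in c(1, 99, 200)) {
    tt <- t.test(M[i, 1:4], M[i, 5:8], var.equal = TRUE)
    expect_equal(abs(tab$t_mod[i]), abs(unname(tt$statistic)),
                 tolerance = 1e-10)
    expect_equal(tab$p[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("p-value adjustment follows Bonferroni and BH step-up", {
  expect_equal(adjust_pvalues(0.01, "bonferroni"), 0.01)
  expect_equal(adjust_pvalues(rep(0.01, 5), "bonferroni"), rep(0.05, 5))
  p <- c(0.01, 0.02, 0.03, 0.04, 0.2, 0.9)
  expect_equal(adjust_pvalues(p, "bh"), c(0.06, 0.06, 0.06, 0.06, 0.24, 0.9))
  expect_equal(adjust_pvalues(rep(1, 4), "bh"), rep(1, 4))
  set.seed(77)
  for (rep in 1:20) {
    q <- runif(sample(3:40, 1))
    adj <- adjust_pvalues(q, "bh")
    expect_equal(adj, bh_oracle(q))
    expect_true(all(adj >= q))
    perm <- sample(length(q))
    expect_equal(adjust_pvalues(q[perm], "bh"), adj[perm])
  }
  expect_error(adjust_pvalues(c(0.1, 1.2), "bh"),
               class = "mircons_validation_error")
})

test_that("DE calling ranks by adjusted p with deterministic tie-breaks", {
  tab <- data.frame(probe_id = c("p1", "p2", "p3", "p4"),
                    beta_hat = c(0.1, -2, 1, 0.5),
                    s2 = 1, df_resid = 4, t_mod = 1,
                    p = c(0.5, 0.001, 0.001, 0),
                    p_adj = c(1, 0.004, 0.004, 0),
                    stringsAsFactors = FALSE)
  calls <- call_de(tab, alpha = 0.01, top_n = 2)
  expect_equal(calls$ranked$probe_id, c("p4", "p2", "p3", "p1"))
  expect_equal(calls$significant$probe_id, c("p4", "p2", "p3"))
  expect_equal(nrow(calls$top), 2L)
  # a zero p-value always ranks first
  expect_equal(calls$ranked$rank[calls$ranked$p_adj == 0], 1L)
})

test_that("the full DE chain recovers planted differential probes", {
  sim <- simulate_two_color_array(400, 10, de_fraction = 0.05,
                                  effect_log2 = 3, seed = 8)
  de <- suppressWarnings(run_array_de(sim, adjust = "bh", alpha = 0.2))
  tab <- de$table
  truth <- sim$truth
  # effect estimates are unbiased for the planted log2 ratios: the
  # regression slope of beta_hat on truth is near 1 (per-probe noise is
  # large by design, so the slope, not the correlation, is the check)
  slope <- coef(lm(tab$beta_hat ~ truth$true_log2_ratio))[2]
  expect_gt(slope, 0.6); expect_lt(slope, 1.4)
  # DE probes dominate the top of the ranking
  top20 <- de$calls$ranked$probe_id[1:20]
  expect_gt(mean(truth$is_de[match(top20, truth$probe_id)]), 0.5)
})
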
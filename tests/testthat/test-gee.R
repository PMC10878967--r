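test_that("independence GEE with one observation per cluster equals Poisson ML", {
  set.seed(21)
  n <- 40
  d <- data.frame(y = rbinom(n, 1, 0.4), treatment = rbinom(n, 1, 0.5),
                  period = sample(1:3, n, TRUE), cluster = seq_len(n))
  fit <- gee_mp(d, outcome = "y", correlation = "independence")
  ref <- glm(y ~ factor(treatment) + factor(period), data = d,
             family = poisson())
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-7)
})

test_that("constant outcome gives a zero treatment effect and log-mean intercept", {
  d <- data.frame(y = rep(1L, 24), treatment = rep(c(0, 1), 12),
                  period = rep(1:2, each = 12), cluster = rep(1:4, each = 6))
  fit <- gee_mp(d, outcome = "y")
  expect_equal(unname(fit$beta[["treatment"]]), 0, tolerance = 1e-10)
  expect_equal(unname(fit$beta[["(Intercept)"]]), log(1), tolerance = 1e-10)
  # perfect fit: both sandwich flavours are exactly zero
  expect_equal(max(abs(sandwich_variance(fit, "sandwich")$matrix)), 0,
               tolerance = 1e-20)
  expect_equal(max(abs(sandwich_variance(fit, "mancl_derouen")$matrix)), 0,
               tolerance = 1e-20)
})

test_that("fit and both sandwich flavours match the dense-matrix oracle", {
  # the printed 3-cluster toy dataset
  toy <- toy_gee_data()
  X <- cbind(1, toy$trt, toy$period == 2, toy$period == 3)
  colnames(X) <- c("(Intercept)", "treatment", "period2", "period3")
  for (corstr in c("exchangeable", "independence")) {
    fit <- gee_mp(toy, outcome = "y", treatment = "trt",
                  correlation = corstr, tol = 1e-10, max_iter = 1000)
    orc <- dense_gee_oracle(toy$y, X, toy$cluster, corstr = corstr,
                            tol = 1e-10, maxit = 1000)
    expect_equal(unname(fit$beta), unname(orc$beta), tolerance = 1e-8)
    expect_equal(fit$alpha, orc$alpha, tolerance = 1e-8)
    expect_equal(fit$phi, orc$phi, tolerance = 1e-8)
    v_sw <- sandwich_variance(fit, "sandwich")$matrix
    v_md <- sandwich_variance(fit, "mancl_derouen")$matrix
    expect_equal(unname(v_sw), unname(dense_sandwich_oracle(orc, "sandwich")),
                 tolerance = 1e-8)
    expect_equal(unname(v_md), unname(dense_sandwich_oracle(orc, "mancl_derouen")),
                 tolerance = 1e-8)
  }
})

test_that("oracle equivalence holds on simulated 5-cluster fixtures, both families", {
  set.seed(99)
  for (rep in 1:3) {
    K <- 5
    d <- do.call(rbind, lapply(1:K, function(k) {
      nk <- sample(6:12, 1)
      data.frame(y = rbinom(nk, 1, 0.45), yd = round(rlnorm(nk, -1, 0.8), 3),
                 treatment = rbinom(nk, 1, 0.5),
                 period = sample(1:3, nk, TRUE), cluster = k)
    }))
    fit <- gee_mp(d, outcome = "y", tol = 1e-10, max_iter = 1000)
    X <- model.matrix(~treatment + factor(period), d)
    orc <- dense_gee_oracle(d$y, X, d$cluster, tol = 1e-10, maxit = 1000)
    expect_equal(unname(fit$beta), unname(orc$beta), tolerance = 1e-8)
    expect_equal(unname(sandwich_variance(fit, "mancl_derouen")$matrix),
                 unname(dense_sandwich_oracle(orc, "mancl_derouen")),
                 tolerance = 1e-8)
    # identity-link Gaussian branch against the same oracle
    fitg <- gee_mp(d, outcome = "yd", family = "gaussian_identity",
                   tol = 1e-10, max_iter = 1000)
    orcg <- dense_gee_oracle(d$yd, X, d$cluster, family = "gaussian_identity",
                             tol = 1e-10, maxit = 1000)
    expect_equal(unname(fitg$beta), unname(orcg$beta), tolerance = 1e-8)
    expect_equal(unname(sandwich_variance(fitg, "sandwich")$matrix),
                 unname(dense_sandwich_oracle(orcg, "sandwich")),
                 tolerance = 1e-8)
  }
})

test_that("Mancl-DeRouen converges to the plain sandwich as clusters grow", {
  rel_diff <- vapply(c(4, 16, 64), function(K) {
    set.seed(1000 + K)
    d <- data.frame(cluster = rep(seq_len(K), each = 8))
    d$period <- rep(rep(1:2, each = 4), K)
    d$treatment <- rbinom(nrow(d), 1, 0.5)
    d$y <- rbinom(nrow(d), 1, 0.4)
    fit <- gee_mp(d, outcome = "y")
    v_sw <- sandwich_variance(fit, "sandwich")$matrix
    v_md <- sandwich_variance(fit, "mancl_derouen")$matrix
    norm(v_md - v_sw, "F") / norm(v_sw, "F")
  }, numeric(1))
  expect_true(all(diff(rel_diff) < 0))
  expect_lt(rel_diff[3], 0.15)
})

test_that("estimates are invariant to row order and cluster relabeling", {
  set.seed(31)
  d <- group1_trial(group1_config(seed = 313, m = 40, cv = 0.2))
  fit <- gee_mp(d, outcome = "cesarean")
  v <- sandwich_variance(fit, "mancl_derouen")$matrix
  perm <- sample(nrow(d))
  d2 <- d[perm, ]
  d2$cluster <- c(10, 30, 20, 40)[d2$cluster]  # relabel
  fit2 <- gee_mp(d2, outcome = "cesarean")
  v2 <- sandwich_variance(fit2, "mancl_derouen")$matrix
  expect_equal(unname(fit$beta), unname(fit2$beta), tolerance = 1e-10)
  expect_equal(unname(v), unname(v2), tolerance = 1e-10)
})

test_that("relative-risk inference uses the t(N-2) reference correctly", {
  d <- group1_trial(group1_config(seed = 55, m = 30, cv = 0.2))
  fit <- gee_mp(d, outcome = "cesarean")
  v <- sandwich_variance(fit, "mancl_derouen")
  est <- effect_estimate(fit, v)
  expect_equal(est$df, 2)
  expect_true(est$ci_low <= est$rr && est$rr <= est$ci_high)
  expect_gt(est$rr, 0)
  # hand computation of the interval
  se <- sqrt(v$matrix["treatment", "treatment"])
  b <- fit$beta[["treatment"]]
  expect_equal(est$ci_low, exp(b - qt(0.975, 2) * se), tolerance = 1e-12)
  expect_equal(est$ci_high, exp(b + qt(0.975, 2) * se), tolerance = 1e-12)
  expect_equal(est$p_value, 2 * pt(-abs(b / se), 2), tolerance = 1e-12)
  # a wider reference gives a strictly wider interval than df = Inf
  est_inf <- effect_estimate(fit, v, df = 1e9)
  expect_lt(est_inf$ci_high - est_inf$ci_low, est$ci_high - est$ci_low)
  # zero effect maps to RR 1 with a log-symmetric interval
  fit0 <- fit
  fit0$beta[["treatment"]] <- 0
  est0 <- effect_estimate(fit0, v)
  expect_equal(est0$rr, 1)
  expect_equal(log(est0$ci_high), -log(est0$ci_low), tolerance = 1e-12)
  expect_error(effect_estimate(fit, v, df = 0), "infeasible")
})

test_that("non-convergence is flagged, never silent", {
  d <- toy_gee_data()
  expect_warning(fit <- gee_mp(d, outcome = "y", treatment = "trt",
                               max_iter = 1), "did not converge")
  expect_false(fit$converged)
  expect_error(sandwich_variance(fit), "converge")
  expect_true(is.matrix(sandwich_variance(fit, allow_nonconverged = TRUE)$matrix))
})

test_that("rank-deficient designs raise an aliasing error naming columns", {
  d <- toy_gee_data()
  d$trt <- 1 - (d$period > 1)  # treatment aliased with period contrast
  expect_error(gee_mp(d, outcome = "y", treatment = "trt"), "aliased")
})

test_that("ICC estimation recovers independence and rejects degenerate input", {
  set.seed(61)
  # independent observations: estimate near zero, lower bound truncated at 0
  d <- data.frame(cesarean = rbinom(2400, 1, 0.4),
                  period = rep(1:4, 600),
                  cluster = rep(1:6, each = 400),
                  condition = "control")
  icc <- estimate_icc(d, n_boot = 60, seed = 3)
  expect_lt(abs(icc$icc), 0.01)
  expect_gte(icc$ci_low, 0)
  expect_lte(icc$ci_low, icc$ci_high)
  # single-member clusters: undefined
  d1 <- data.frame(cesarean = rbinom(6, 1, 0.5), period = 1,
                   cluster = 1:6, condition = "control")
  expect_error(estimate_icc(d1), "single member")
  # too few clusters for the bootstrap
  d2 <- d[d$cluster <= 2, ]
  expect_error(estimate_icc(d2, n_boot = 10), "fewer than 3")
})

test_that("mean differences recover an injected duration shift", {
  set.seed(71)
  d <- group1_trial(group1_config(seed = 717, m = 60, cv = 0.2))
  base <- rlnorm(nrow(d), log(0.3), 0.5)
  d$dur <- round(base + 0.5 * d$treatment, 3)
  md <- mean_difference(d, outcome = "dur")
  expect_equal(md$difference, 0.5, tolerance = 0.05)
  expect_true(md$ci_low < md$coef_difference & md$coef_difference < md$ci_high)
  expect_equal(md$df, 2)
  # identical distributions: difference near zero
  d$dur0 <- round(base, 3)
  md0 <- mean_difference(d, outcome = "dur0")
  expect_lt(abs(md0$difference), 0.05)
  # all-missing durations rejected
  d$gone <- NA_real_
  expect_error(mean_difference(d, outcome = "gone"), "empty outcome")
})
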
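test_that("variance-component solver hits its targets and handles edge cases", {
  vc <- solve_variance_components(0.02, 0.90, 0.40)
  expect_equal(vc$achieved$icc, 0.02, tolerance = 1e-8)
  expect_equal(vc$achieved$cac, 0.90, tolerance = 1e-6)
  expect_gt(vc$cluster_sd, vc$cluster_period_sd)
  # icc = 0: no random effects at all
  vc0 <- solve_variance_components(0, 0.5, 0.3)
  expect_equal(vc0$cluster_sd, 0)
  expect_equal(vc0$cluster_period_sd, 0)
  # cac = 1: all variance at cluster level
  vc1 <- solve_variance_components(0.05, 1, 0.3)
  expect_equal(vc1$cluster_period_sd, 0)
  expect_equal(vc1$achieved$icc, 0.05, tolerance = 1e-8)
  # unattainable target
  expect_error(solve_variance_components(0.999, 0.9, 0.4), "infeasible")
})

test_that("solved components induce the target correlation in the latent model", {
  # large-sample Monte-Carlo check of the solver, directly on the
  # latent-effect model the generator draws from
  vc <- solve_variance_components(0.02, 0.90, 0.40)
  set.seed(202)
  n <- 4e6
  u <- rnorm(n, 0, vc$cluster_sd)
  f1 <- plogis(vc$intercept + u + rnorm(n, 0, vc$cluster_period_sd))
  f2 <- plogis(vc$intercept + u + rnorm(n, 0, vc$cluster_period_sd))
  mu <- mean(f1)
  within <- mean(f1^2) - mu^2          # + Bernoulli noise handled analytically:
  icc_hat <- within / (mu * (1 - mu))  # corr of two women sharing (u, v)
  between_hat <- (mean(f1 * f2) - mu^2) / (mu * (1 - mu))
  expect_equal(mu, 0.40, tolerance = 1e-3)
  expect_equal(icc_hat, 0.02, tolerance = 1e-3)
  expect_equal(between_hat, 0.02 * 0.90, tolerance = 1e-3)
})

test_that("generated records always pass profile validation and classify cleanly", {
  d <- generate_trial(generator_config(seed = 3, mean_cluster_period_size = 150))
  expect_false(anyNA(robson_classify(d)))        # strict mode, no error
  expect_true(all(d$previous_cs <= d$parity))
  expect_true(all(d$gestational_age_weeks >= 20))
  # denominator logic of the record schema
  expect_true(all(is.na(d$augmentation[d$labor_onset != "spontaneous"])))
  expect_true(all(!is.na(d$augmentation[d$labor_onset == "spontaneous"])))
  expect_true(all(is.na(d$episiotomy[d$cesarean == 1])))
  expect_true(all(!is.na(d$operative_vaginal[d$cesarean == 0])))
  # cesarean and operative vaginal birth are mutually exclusive
  expect_true(all(d$cesarean == 1 | d$operative_vaginal %in% c(0, 1)))
  expect_false(any(d$cesarean == 1 & !is.na(d$operative_vaginal) &
                     d$operative_vaginal == 1))
  # prelabor cesarean implies cesarean
  expect_true(all(d$cesarean[d$labor_onset == "prelabor_cesarean"] == 1))
  # babies counts are consistent
  expect_true(all(d$n_stillbirths <= d$n_babies))
  expect_true(all(d$n_neonatal_deaths <= d$n_babies - d$n_stillbirths))
  # survey subsample only in Robson 1 or 3 with a liveborn baby
  sv <- d[d$surveyed == 1, ]
  expect_true(all(sv$robson_group %in% c(1, 3)))
  expect_true(all(sv$n_babies - sv$n_stillbirths >= 1))
})

test_that("null generator at icc 0 reproduces the baseline rate binomially", {
  cfg <- group1_config(seed = 909, p0 = 0.40, rr = 1, m = 150, cv = 0,
                       icc = 0, cac = 0.9)
  d <- group1_trial(cfg)
  p_hat <- mean(d$cesarean)
  se <- sqrt(0.4 * 0.6 / nrow(d))
  expect_lt(abs(p_hat - 0.40), 4 * se)
})

test_that("empirical outcome-scale correlation of generator output matches targets", {
  # a wider wedge so the cluster-level MC error on the ICC is manageable;
  # averaged over independent seeds
  des <- sw_design(20, n_periods = 21, transition_days = 0)
  wi <- bw <- numeric(10)
  for (s in seq_len(10)) {
    cfg <- group1_config(seed = 5000 + s, p0 = 0.40, rr = 1, m = 60, cv = 0,
                         icc = 0.02, cac = 0.90, design = des)
    d <- generate_trial(cfg)
    e <- empirical_icc(d$cesarean, d$cluster, d$period)
    wi[s] <- e["within"]; bw[s] <- e["between"]
  }
  expect_lt(abs(mean(wi) - 0.02), 0.005)
  expect_lt(abs(mean(bw) - 0.018), 0.005)
})

test_that("generation is reproducible: same seed, byte-identical CSV", {
  cfg <- generator_config(seed = 42, mean_cluster_period_size = 40)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_birth_records(generate_trial(cfg), f1)
  write_birth_records(generate_trial(cfg), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # a different seed produces different data
  f3 <- tempfile(fileext = ".csv")
  write_birth_records(generate_trial(generator_config(
    seed = 43, mean_cluster_period_size = 40)), f3)
  expect_false(identical(readBin(f1, "raw", file.size(f1)),
                         readBin(f3, "raw", file.size(f3))))
})

test_that("CSV round trip is lossless and schema violations are caught", {
  d <- generate_trial(generator_config(seed = 8, mean_cluster_period_size = 50))
  path <- tempfile(fileext = ".csv")
  write_birth_records(d, path)
  expect_true(file.exists(paste0(path, ".dict.json")))
  back <- read_birth_records(path)
  rownames(d) <- NULL
  expect_equal(back, d[, names(back)], ignore_attr = TRUE)
  # missing column
  broken <- read.csv(path)
  broken$cesarean <- NULL
  pb <- tempfile(fileext = ".csv")
  write.csv(broken, pb, row.names = FALSE)
  expect_error(read_birth_records(pb), "missing column")
  # unknown column
  extra <- read.csv(path)
  extra$mystery <- 1
  pe <- tempfile(fileext = ".csv")
  write.csv(extra, pe, row.names = FALSE)
  expect_error(read_birth_records(pe), "unknown column")
})

test_that("a trial-sized dataset round-trips quickly", {
  d <- generate_trial(generator_config(seed = 26331))
  expect_gt(nrow(d), 20000)
  path <- tempfile(fileext = ".csv")
  elapsed <- system.time({
    write_birth_records(d, path)
    back <- read_birth_records(path)
  })[["elapsed"]]
  expect_equal(nrow(back), nrow(d))
  expect_lt(elapsed, 10)
})
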
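test_that("named clinical examples classify to the expected groups", {
  prof <- function(parity, prev, onset, pres, nf, ga) {
    data.frame(parity = parity, previous_cs = prev, labor_onset = onset,
               presentation = pres, n_fetuses = nf,
               gestational_age_weeks = ga)
  }
  # nulliparous singleton term cephalic spontaneous labor
  expect_equal(robson_classify(prof(0, 0, "spontaneous", "cephalic", 1, 39)), 1L)
  # multiple pregnancy dominates everything else
  expect_equal(robson_classify(prof(2, 1, "induced", "cephalic", 2, 38)), 8L)
  # oblique lie, regardless of onset
  expect_equal(robson_classify(prof(1, 0, "induced", "transverse_oblique", 1, 40)), 9L)
  # previous cesarean, term cephalic singleton
  expect_equal(robson_classify(prof(2, 1, "spontaneous", "cephalic", 1, 40)), 5L)
  # preterm cephalic trumps previous cesarean
  expect_equal(robson_classify(prof(2, 1, "spontaneous", "cephalic", 1, 34)), 10L)
  # breech by parity
  expect_equal(robson_classify(prof(0, 0, "induced", "breech", 1, 39)), 6L)
  expect_equal(robson_classify(prof(3, 2, "prelabor_cesarean", "breech", 1, 39)), 7L)
})

test_that("classification matches the hand-encoded manual oracle on the full grid", {
  grid <- expand.grid(parity = c(0L, 1L), previous_cs = c(0L, 1L),
                      labor_onset = c("spontaneous", "induced", "prelabor_cesarean"),
                      presentation = c("cephalic", "breech", "transverse_oblique"),
                      n_fetuses = c(1L, 2L),
                      gestational_age_weeks = c(34, 39),
                      stringsAsFactors = FALSE)
  expect_equal(nrow(grid), 144)
  valid <- grid$previous_cs <= grid$parity
  got <- robson_classify(grid[valid, ])
  want <- mapply(robson_oracle, grid$parity[valid], grid$previous_cs[valid],
                 grid$labor_onset[valid], grid$presentation[valid],
                 grid$n_fetuses[valid], grid$gestational_age_weeks[valid])
  expect_equal(got, unname(want))
  # invariant-violating cells raise a validation error naming the field
  expect_error(robson_classify(grid), "previous_cs")
})

test_that("classification is total and single-valued over random profiles", {
  set.seed(404)
  n <- 4000
  prof <- data.frame(
    parity = rpois(n, 1),
    labor_onset = sample(c("spontaneous", "induced", "prelabor_cesarean"), n, TRUE),
    presentation = sample(c("cephalic", "breech", "transverse_oblique"), n, TRUE),
    n_fetuses = 1L + rbinom(n, 2, 0.05),
    gestational_age_weeks = runif(n, 20, 43))
  prof$previous_cs <- pmin(rpois(n, 0.5), prof$parity)
  g <- robson_classify(prof)
  expect_false(anyNA(g))
  expect_true(all(g %in% 1:10))
  # term threshold behaves as a sharp boundary
  at <- prof$gestational_age_weeks >= 37
  ceph_single <- prof$presentation == "cephalic" & prof$n_fetuses == 1
  expect_true(all(g[ceph_single & !at] == 10))
  expect_true(all(g[ceph_single & at] != 10))
})

test_that("robson_table satisfies the WHO column identities", {
  set.seed(7)
  d <- generate_trial(generator_config(seed = 77, mean_cluster_period_size = 60))
  tab <- robson_table(d)
  expect_equal(sum(tab$n_women), nrow(d))
  expect_equal(sum(tab$group_size_pct), 100, tolerance = 1e-12)
  expect_equal(sum(tab$absolute_contribution_pct),
               attr(tab, "overall_cs_rate_pct"), tolerance = 1e-12)
  expect_equal(sum(tab$relative_contribution_pct), 100, tolerance = 1e-12)
  # permuting record order changes nothing
  perm <- sample(nrow(d))
  expect_equal(as.data.frame(robson_table(d[perm, ])), as.data.frame(tab))
  # degenerate table: one group, all cesarean
  one <- data.frame(robson_group = rep(5L, 8), cesarean = 1L)
  t1 <- robson_table(one)
  expect_equal(t1$relative_contribution_pct[5], 100)
  expect_equal(t1$n_women[5], 8L)
  expect_equal(sum(t1$n_women[-5]), 0L)
  expect_error(robson_table(data.frame()), "empty")
})

test_that("group size percentage reproduces the control-period share arithmetic", {
  # 3,543 Group-1 women of 11,517 -> 30.8%
  expect_equal(round_half_up(100 * 3543 / 11517, 1), 30.8)
})

test_that("monthly feedback reports are consistent with tabulation and additive", {
  d <- generate_trial(generator_config(seed = 11, mean_cluster_period_size = 80))
  rep1 <- robson_monthly_report(d, "2021-09")
  slice <- d[format(d$date, "%Y-%m") == "2021-09", ]
  expect_equal(as.data.frame(rep1$table), as.data.frame(robson_table(slice)))
  # trend has one point per month up to the report month
  months <- sort(unique(format(d$date[format(d$date, "%Y-%m") <= "2021-09"], "%Y-%m")))
  expect_equal(rep1$trend$month, months)
  # a month with no births is an explicit empty report, not an error
  none <- robson_monthly_report(d[format(d$date, "%Y-%m") != "2021-08", ], "2021-08")
  expect_null(none$table)
  expect_output(print(none), "No births")
  # month boundaries put each record in exactly one month
  counts <- vapply(sort(unique(format(d$date, "%Y-%m"))), function(m) {
    r <- robson_monthly_report(d, m)
    if (is.null(r$table)) 0L else attr(r$table, "n_total")
  }, integer(1))
  expect_equal(sum(counts), nrow(d))
  # month-wise tables aggregate to the whole-period table
  per_month <- lapply(sort(unique(format(d$date, "%Y-%m"))), function(m) {
    robson_monthly_report(d, m)$table
  })
  agg_women <- Reduce(`+`, lapply(per_month, function(t) t$n_women))
  expect_equal(agg_women, robson_table(d)$n_women)
  # invalid rows are excluded and counted in the footer
  dbad <- d
  dbad$labor_onset[1:3] <- "unknown"
  repb <- robson_monthly_report(dbad[, setdiff(names(dbad), "robson_group")], "2021-09")
  expect_equal(repb$n_invalid, 3L)
})
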
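# Gauss-Hermite nodes/weights (Golub-Welsch), cached at package load.
# Standardized so that for s ~ N(0, sigma^2): E f(s) = sum w_j f(sigma * x_j).
gh_rule <- function(k = 40) {
  i <- seq_len(k - 1)
  b <- sqrt(i / 2)
  Jm <- matrix(0, k, k)
  Jm[cbind(i, i + 1)] <- b
  Jm[cbind(i + 1, i)] <- b
  eig <- eigen(Jm, symmetric = TRUE)
  nodes <- eig$values * sqrt(2)              # standard-normal scaling
  weights <- eig$vectors[1, ]^2              # already sum to 1
  ord <- order(nodes)
  list(x = nodes[ord], w = weights[ord])
}
.gh <- gh_rule(40)

# memo for solved variance components (repeated identically across
# simulation replicates)
.vc_cache <- new.env(parent = emptyenv())

# marginal mean, within-cell and between-period covariances of
# plogis(eta0 + u + v), u ~ N(0, s2c), v ~ N(0, s2p)
latent_moments <- function(eta0, s2c, s2p) {
  x <- .gh$x; w <- .gh$w
  su <- sqrt(s2c); sv <- sqrt(s2p)
  # g(u) = E_v plogis(eta0 + u + v); vectorized over outer nodes
  pm <- outer(su * x, sv * x, function(u, v) stats::plogis(eta0 + u + v))
  g <- drop(pm %*% w)                 # per u-node
  g2 <- drop((pm^2) %*% w)            # E_v f^2 per u-node
  mu <- sum(w * g)
  within <- sum(w * g2) - mu^2        # Var over (u, v) jointly
  between <- sum(w * g^2) - mu^2      # Var_u of E_v f
  list(mu = mu, within = within, between = between)
}

# intercept giving marginal mean p under total latent variance tau2
latent_intercept <- function(p, tau2) {
  if (tau2 <= 0) return(stats::qlogis(p))
  f <- function(eta0) sum(.gh$w * stats::plogis(eta0 + sqrt(tau2) * .gh$x)) - p
  stats::uniroot(f, c(stats::qlogis(p) - 10 - 3 * sqrt(tau2),
                      stats::qlogis(p) + 10 + 3 * sqrt(tau2)),
                 tol = 1e-12)$root
}

#' Latent-scale variance components for target ICC and CAC
#'
#' The generator induces within-cluster correlation through nested normal
#' random effects on the logit scale: a cluster effect `u` (SD
#' `cluster_sd`) shared by all of a cluster's women, plus a cluster-period
#' effect `v` (SD `cluster_period_sd`) shared within one period. Design
#' targets, however, are stated on the outcome (proportion) scale: the ICC
#' `rho` is the correlation of two women in the same cluster and period, and
#' the cluster autocorrelation `r` is the ratio of the between-period to the
#' within-period correlation. This solver bridges the scales: it finds the
#' two SDs (by nested bisection with Gauss-Hermite quadrature for the
#' logit-normal moments, re-centering the intercept so the marginal mean
#' stays at `baseline_p`) such that the induced outcome-scale ICC equals
#' `icc` and the between-period correlation equals `icc * cac`. The solve is
#' deterministic.
#'
#' @param icc target outcome-scale ICC in `[0, 1)`.
#' @param cac target cluster autocorrelation in `[0, 1]`.
#' @param baseline_p marginal outcome probability at which the targets are
#'   calibrated (strictly inside (0, 1)).
#' @return List with `cluster_sd`, `cluster_period_sd`, the calibrated
#'   `intercept`, and `achieved` (quadrature-checked ICC and CAC).
#' @examples
#' solve_variance_components(0.02, 0.90, 0.40)
#' @export
solve_variance_components <- function(icc, cac, baseline_p) {
  stopifnot(icc >= 0, icc < 1, cac >= 0, cac <= 1,
            baseline_p > 0, baseline_p < 1)
  key <- sprintf("%.12g|%.12g|%.12g", icc, cac, baseline_p)
  if (!is.null(.vc_cache[[key]])) return(.vc_cache[[key]])
  on.exit(if (exists("out", inherits = FALSE)) .vc_cache[[key]] <- out)
  if (icc == 0) {
    return(list(cluster_sd = 0, cluster_period_sd = 0,
                intercept = stats::qlogis(baseline_p),
                achieved = list(icc = 0, cac = cac)))
  }
  sig2 <- function(s2c, s2p) {
    eta0 <- latent_intercept(baseline_p, s2c + s2p)
    m <- latent_moments(eta0, s2c, s2p)
    list(rho = m$within / (m$mu * (1 - m$mu)), between = m$between,
         within = m$within)
  }
  tau2_max <- 400
  if (sig2(tau2_max, 0)$rho < icc) {
    stop(sprintf(
      "infeasible ICC target %.4g at baseline %.3g; attainable maximum ~%.4g",
      icc, baseline_p, sig2(tau2_max, 0)$rho), call. = FALSE)
  }
  # total variance tau2 such that outcome ICC = icc, for a given split:
  # outcome ICC depends (weakly) on the split, so solve tau2 given share
  solve_tau2 <- function(share_c) {
    f <- function(tau2) sig2(share_c * tau2, (1 - share_c) * tau2)$rho - icc
    stats::uniroot(f, c(1e-10, tau2_max), tol = 1e-12)$root
  }
  if (cac >= 1) {
    tau2 <- solve_tau2(1)
    out <- list(cluster_sd = sqrt(tau2), cluster_period_sd = 0)
  } else if (cac <= 0) {
    tau2 <- solve_tau2(0)
    out <- list(cluster_sd = 0, cluster_period_sd = sqrt(tau2))
  } else {
    # outer bisection on the cluster share of latent variance: the induced
    # CAC rises monotonically from 0 (share 0) to 1 (share 1)
    g <- function(share_c) {
      tau2 <- solve_tau2(share_c)
      m <- sig2(share_c * tau2, (1 - share_c) * tau2)
      m$between / m$within - cac
    }
    share <- stats::uniroot(g, c(1e-10, 1 - 1e-10), tol = 1e-10)$root
    tau2 <- solve_tau2(share)
    out <- list(cluster_sd = sqrt(share * tau2),
                cluster_period_sd = sqrt((1 - share) * tau2))
  }
  eta0 <- latent_intercept(baseline_p, out$cluster_sd^2 + out$cluster_period_sd^2)
  m <- latent_moments(eta0, out$cluster_sd^2, out$cluster_period_sd^2)
  out$intercept <- eta0
  out$achieved <- list(icc = m$within / (m$mu * (1 - m$mu)),
                       cac = if (m$within > 0) m$between / m$within else cac)
  out
}

#' Configuration for the synthetic trial generator
#'
#' Defaults emulate a four-hospital stepped-wedge trial of intrapartum care
#' in high-volume hospitals: roughly 1,100 women per hospital per 2-month
#' period with a coefficient of variation of 0.60, the covariate mix of the
#' trial population (47% nulliparous; among multiparous women 56%/35.5%/8.5%
#' with 0/1/2+ previous cesareans; ~1% multiple pregnancies; 3.5% breech and
#' 0.5% transverse lie; gestational age centred on 38.3 weeks), group-
#' specific baseline cesarean probabilities that reproduce the trial's
#' Robson mix and overall cesarean rate near 50%, an intervention relative
#' risk applied to cesarean among laboring women (default 0.85, the scale of
#' effect the trial was reading), and outcome-scale ICC 0.02 with cluster
#' autocorrelation 0.90 calibrated at the Robson Group 1 baseline.
#'
#' @param design an [sw_design()]; default [default_trial_design()].
#' @param mean_cluster_period_size mean women per cluster per full-length
#'   period (truncated periods scale proportionally).
#' @param cv_cluster_size coefficient of variation of cluster-period size
#'   (log-normal).
#' @param p_nulliparous probability a woman is nulliparous.
#' @param p_prev_cs_multip probabilities of 0, 1 and 2 previous cesareans
#'   among multiparous women (sums to 1).
#' @param p_onset probabilities of spontaneous, induced and prelabor-
#'   cesarean onset (sums to 1).
#' @param p_presentation probabilities of cephalic, breech and transverse/
#'   oblique presentation (sums to 1).
#' @param p_multiple probability of a twin pregnancy.
#' @param ga_term_mean,ga_term_sd,ga_preterm_mean,ga_preterm_sd,p_early
#'   gestational age (weeks) is a two-component normal mixture — a dominant
#'   term component and an early-delivery component with probability
#'   `p_early` — truncated to `[20, 43]`. The defaults give mean ~38.4 and
#'   SD ~2.4 with ~12% of births before 37 weeks, matching the study
#'   population's printed mean (38.3, SD 2.5) while keeping the preterm
#'   fraction (hence Robson Group 10) realistic; a single normal at that
#'   mean and SD would put over 20% of births preterm.
#' @param cs_baseline named numeric: baseline (control) cesarean probability
#'   per Robson group for women who labor; prelabor-cesarean women are
#'   cesarean by definition.
#' @param cesarean_rr intervention relative risk on cesarean among laboring
#'   women.
#' @param icc,cac outcome-scale correlation targets; calibrated at the
#'   Robson Group 1 control baseline.
#' @param augmentation_p,augmentation_rr baseline probability and
#'   intervention RR of oxytocin augmentation (defined among spontaneous
#'   labor).
#' @param arm_p,arm_rr artificial rupture of membranes (spontaneous labor).
#' @param episiotomy_p,episiotomy_rr episiotomy (vaginal births).
#' @param opvb_p,opvb_rr operative vaginal birth (vaginal births).
#' @param stillbirth_p,neonatal_death_p per-baby adverse outcome
#'   probabilities.
#' @param adm_birth_days,birth_dis_days `c(mean, sd)` of the log-normal
#'   admission-to-childbirth and childbirth-to-discharge durations (days),
#'   control arm.
#' @param adm_birth_days_int,birth_dis_days_int same for the intervention
#'   arm.
#' @param survey_window_days women in Robson Group 1 or 3 with a liveborn
#'   baby delivering in the last `survey_window_days` days of a period are
#'   flagged as the postpartum-survey subsample.
#' @param seed mandatory integer seed; the same seed reproduces the same
#'   dataset byte for byte.
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(design = default_trial_design(),
                             mean_cluster_period_size = 1100,
                             cv_cluster_size = 0.60,
                             p_nulliparous = 0.47,
                             p_prev_cs_multip = c(`0` = 0.56, `1` = 0.355, `2` = 0.085),
                             p_onset = c(spontaneous = 0.76, induced = 0.14,
                                         prelabor_cesarean = 0.10),
                             p_presentation = c(cephalic = 0.96, breech = 0.035,
                                                transverse_oblique = 0.005),
                             p_multiple = 0.01,
                             ga_term_mean = 39.1, ga_term_sd = 1.1,
                             ga_preterm_mean = 32.5, ga_preterm_sd = 3.0,
                             p_early = 0.10,
                             cs_baseline = c(`1` = 0.452, `2` = 0.60, `3` = 0.119,
                                             `4` = 0.45, `5` = 0.75, `6` = 0.93,
                                             `7` = 0.92, `8` = 0.80, `9` = 0.97,
                                             `10` = 0.35),
                             cesarean_rr = 0.85,
                             icc = 0.02, cac = 0.90,
                             augmentation_p = 0.273, augmentation_rr = 0.34,
                             arm_p = 0.067, arm_rr = 0.85,
                             episiotomy_p = 0.55, episiotomy_rr = 1.0,
                             opvb_p = 0.0196, opvb_rr = 1.0,
                             stillbirth_p = 0.032, neonatal_death_p = 0.017,
                             adm_birth_days = c(0.30, 0.68),
                             birth_dis_days = c(3.52, 1.88),
                             adm_birth_days_int = c(0.34, 0.73),
                             birth_dis_days_int = c(3.29, 1.75),
                             survey_window_days = 15,
                             seed = NULL) {
  if (is.null(seed)) stop("a seed is mandatory for reproducible generation",
                          call. = FALSE)
  stopifnot(inherits(design, "sw_design"),
            mean_cluster_period_size > 0, cv_cluster_size >= 0,
            icc >= 0, icc < 1, cac >= 0, cac <= 1)
  probs <- c(p_nulliparous, p_prev_cs_multip, p_onset, p_presentation,
             p_multiple, cs_baseline, augmentation_p, arm_p, episiotomy_p,
             opvb_p, stillbirth_p, neonatal_death_p)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]",
                                       call. = FALSE)
  for (v in list(p_prev_cs_multip, p_onset, p_presentation)) {
    if (abs(sum(v) - 1) > 1e-8) stop("categorical probabilities must sum to 1",
                                     call. = FALSE)
  }
  cfg <- as.list(environment())
  class(cfg) <- "generator_config"
  cfg
}

# moment-matched log-normal draw
rlnorm_ms <- function(n, mean, sd) {
  if (mean <= 0) return(rep(0, n))
  s2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Generate an individual-level synthetic stepped-wedge trial
#'
#' Draws a full one-row-per-woman dataset from a [generator_config()]:
#' log-normal cluster-period sizes, obstetric covariates, Robson groups via
#' [robson_classify()], cesarean assigned through the latent logit-normal
#' cluster and cluster-period effects (so the outcome-scale ICC and CAC hit
#' the configured targets), and secondary outcomes respecting the trial's
#' denominator logic: augmentation and artificial rupture of membranes are
#' defined only for spontaneous labor, episiotomy and operative vaginal
#' birth only for vaginal births, cesarean and operative vaginal birth are
#' mutually exclusive, and prelabor-cesarean women are cesarean by
#' definition. Women delivering inside a cluster's transition window carry
#' `condition = "transition"`.
#'
#' Marginal cesarean probabilities after relative-risk scaling are clamped
#' to at most 0.999 before the latent solve; the number of clamped cells is
#' recorded in `attr(, "n_clamped")`.
#'
#' @param config a [generator_config()].
#' @return Data frame of synthetic birth records (one row per woman; babies
#'   are counted by `n_babies`), with attributes `n_clamped` and `config`.
#' @examples
#' d <- generate_trial(generator_config(seed = 7,
#'   mean_cluster_period_size = 50))
#' table(d$condition)
#' @export
generate_trial <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cf <- config
  des <- cf$design
  set.seed(as.integer(cf$seed))
  K <- des$n_clusters
  T <- des$n_periods
  wt <- des$period_days / des$period_length_days

  # cluster-period sizes: log-normal around the period-length-scaled mean
  grid <- expand.grid(cluster = seq_len(K), period = seq_len(T))
  grid$mean_size <- cf$mean_cluster_period_size * wt[grid$period]
  grid$size <- if (cf$cv_cluster_size > 0) {
    pmax(1L, as.integer(round(rlnorm_ms(nrow(grid), 1, cf$cv_cluster_size) *
                                grid$mean_size)))
  } else {
    pmax(1L, as.integer(round(grid$mean_size)))
  }
  n <- sum(grid$size)
  cluster <- rep(grid$cluster, grid$size)
  period <- rep(grid$period, grid$size)

  # birth dates uniform within each period
  pstart <- as.numeric(des$period_start)[period]
  pdays <- des$period_days[period]
  date <- as.Date(floor(pstart + stats::runif(n) * pdays),
                  origin = "1970-01-01")
  condition <- sw_condition(des, cluster, date)
  treatment <- as.integer(condition == "intervention")

  # obstetric covariates
  nullip <- stats::rbinom(n, 1, cf$p_nulliparous) == 1
  parity <- integer(n)
  nm <- sum(!nullip)
  parity[!nullip] <- 1L + stats::rbinom(nm, 3, 0.18)   # mostly parity 1-3
  prev_cs <- integer(n)
  prev_cs[!nullip] <- sample(0:2, nm, replace = TRUE, prob = cf$p_prev_cs_multip)
  prev_cs <- pmin(prev_cs, parity)
  onset <- sample(names(cf$p_onset), n, replace = TRUE, prob = cf$p_onset)
  presentation <- sample(names(cf$p_presentation), n, replace = TRUE,
                         prob = cf$p_presentation)
  n_fetuses <- 1L + stats::rbinom(n, 1, cf$p_multiple)
  early <- stats::rbinom(n, 1, cf$p_early) == 1
  ga <- ifelse(early,
               stats::rnorm(n, cf$ga_preterm_mean, cf$ga_preterm_sd),
               stats::rnorm(n, cf$ga_term_mean, cf$ga_term_sd))
  # recorded to 0.1 weeks before classification so a written-and-reread
  # dataset classifies identically
  ga <- round(pmin(pmax(ga, 20), 43), 1)

  profiles <- data.frame(parity = parity, previous_cs = prev_cs,
                         labor_onset = onset, presentation = presentation,
                         n_fetuses = n_fetuses, gestational_age_weeks = ga)
  group <- robson_classify(profiles)

  # latent random effects shared across correlated outcomes, calibrated at
  # the Robson Group 1 control baseline
  vc <- solve_variance_components(cf$icc, cf$cac, cf$cs_baseline[["1"]])
  u <- stats::rnorm(K, 0, vc$cluster_sd)
  v <- matrix(stats::rnorm(K * T, 0, vc$cluster_period_sd), K, T)
  re <- u[cluster] + v[cbind(cluster, period)]

  n_clamped <- 0L
  tau2 <- vc$cluster_sd^2 + vc$cluster_period_sd^2
  # marginal -> conditional intercept, memoized over the few distinct cells
  intercept_for <- local({
    cache <- new.env(parent = emptyenv())
    function(p) {
      key <- sprintf("%.12g", p)
      if (is.null(cache[[key]])) cache[[key]] <- latent_intercept(p, tau2)
      cache[[key]]
    }
  })
  draw_correlated <- function(p_marginal) {
    n_clamped <<- n_clamped + sum(p_marginal > 0.999 & !duplicated(p_marginal))
    p_marginal <- pmin(p_marginal, 0.999)
    up <- unique(p_marginal)                 # a handful of distinct cells
    e0 <- vapply(up, intercept_for, numeric(1))
    eta0 <- e0[match(p_marginal, up)]
    stats::rbinom(length(p_marginal), 1, stats::plogis(eta0 + re))
  }

  labors <- onset != "prelabor_cesarean"
  p_cs <- unname(cf$cs_baseline[as.character(group)]) *
    ifelse(treatment == 1, cf$cesarean_rr, 1)
  cesarean <- draw_correlated(p_cs)
  cesarean[!labors] <- 1L

  spont <- onset == "spontaneous"
  rrf <- function(rr) ifelse(treatment == 1, rr, 1)
  augmentation <- ifelse(spont,
                         draw_correlated(pmin(cf$augmentation_p * rrf(cf$augmentation_rr), 0.999)),
                         NA_integer_)
  arm <- ifelse(spont, stats::rbinom(n, 1, pmin(cf$arm_p * rrf(cf$arm_rr), 1)),
                NA_integer_)
  vaginal <- cesarean == 0L
  episiotomy <- ifelse(vaginal,
                       draw_correlated(pmin(cf$episiotomy_p * rrf(cf$episiotomy_rr), 0.999)),
                       NA_integer_)
  opvb <- ifelse(vaginal,
                 stats::rbinom(n, 1, pmin(cf$opvb_p * rrf(cf$opvb_rr), 1)),
                 NA_integer_)

  n_babies <- n_fetuses
  n_stillbirths <- stats::rbinom(n, n_babies, cf$stillbirth_p)
  liveborn <- n_babies - n_stillbirths
  n_neonatal_deaths <- stats::rbinom(n, liveborn, cf$neonatal_death_p)

  int_arm <- treatment == 1
  adm <- numeric(n)
  dis <- numeric(n)
  adm[!int_arm] <- rlnorm_ms(sum(!int_arm), cf$adm_birth_days[1], cf$adm_birth_days[2])
  adm[int_arm] <- rlnorm_ms(sum(int_arm), cf$adm_birth_days_int[1], cf$adm_birth_days_int[2])
  dis[!int_arm] <- rlnorm_ms(sum(!int_arm), cf$birth_dis_days[1], cf$birth_dis_days[2])
  dis[int_arm] <- rlnorm_ms(sum(int_arm), cf$birth_dis_days_int[1], cf$birth_dis_days_int[2])
  # recorded to ~1.5-minute precision, as a register would hold them
  adm <- round(adm, 3)
  dis <- round(dis, 3)

  pend <- as.numeric(des$period_end)[period]
  surveyed <- as.integer(group %in% c(1L, 3L) & liveborn >= 1L &
                           as.numeric(date) > pend - cf$survey_window_days)

  out <- data.frame(
    woman_id = seq_len(n),
    cluster = cluster,
    date = date,
    period = period,
    condition = condition,
    parity = parity,
    previous_cs = prev_cs,
    labor_onset = onset,
    presentation = presentation,
    n_fetuses = n_fetuses,
    gestational_age_weeks = ga,
    robson_group = group,
    cesarean = cesarean,
    augmentation = augmentation,
    arm = arm,
    episiotomy = episiotomy,
    operative_vaginal = opvb,
    n_babies = n_babies,
    n_stillbirths = n_stillbirths,
    n_neonatal_deaths = n_neonatal_deaths,
    days_admission_to_birth = adm,
    days_birth_to_discharge = dis,
    surveyed = surveyed,
    stringsAsFactors = FALSE)
  attr(out, "n_clamped") <- n_clamped
  attr(out, "config") <- cf
  if (n_clamped > 0) {
    warning(n_clamped, " outcome cell(s) had RR-scaled probability > 0.999 ",
            "and were clamped", call. = FALSE)
  }
  out
}

# package data dictionary: column name, type, definition
birth_record_dictionary <- function() {
  data.frame(
    column = c("woman_id", "cluster", "date", "period", "condition", "parity",
               "previous_cs", "labor_onset", "presentation", "n_fetuses",
               "gestational_age_weeks", "robson_group", "cesarean",
               "augmentation", "arm", "episiotomy", "operative_vaginal",
               "n_babies", "n_stillbirths", "n_neonatal_deaths",
               "days_admission_to_birth", "days_birth_to_discharge",
               "surveyed"),
    type = c("integer", "integer", "date", "integer", "character", "integer",
             "integer", "character", "character", "integer", "numeric",
             "integer", "integer", "integer", "integer", "integer", "integer",
             "integer", "integer", "integer", "numeric", "numeric", "integer"),
    definition = c(
      "unique woman identifier",
      "hospital (randomization unit) id",
      "date of birth event (ISO 8601)",
      "analysis period index",
      "planned condition at birth: control / transition / intervention",
      "previous births before this pregnancy",
      "previous cesarean sections (<= parity)",
      "labor onset: spontaneous / induced / prelabor_cesarean",
      "fetal presentation: cephalic / breech / transverse_oblique",
      "number of fetuses this pregnancy",
      "gestational age at birth, weeks",
      "Robson ten-group classification (1-10)",
      "birth by cesarean section (0/1)",
      "oxytocin augmentation; only defined for spontaneous labor",
      "artificial rupture of membranes; only defined for spontaneous labor",
      "episiotomy; only defined for vaginal births",
      "operative vaginal birth; only defined for vaginal births",
      "babies delivered (= n_fetuses)",
      "stillborn babies among them",
      "neonatal deaths among liveborn babies",
      "days from admission to childbirth",
      "days from childbirth to discharge",
      "postpartum-survey subsample member (Robson 1 or 3, liveborn, born in the last days of a period)"),
    stringsAsFactors = FALSE)
}

#' Write / read synthetic birth records
#'
#' `write_birth_records()` writes records as plain CSV with a JSON data
#' dictionary alongside (`<path>.dict.json`); `read_birth_records()` reads
#' them back, validating the schema. The round trip is lossless and the same
#' generator seed produces a byte-identical file.
#'
#' @param records data frame from [generate_trial()] (or the same schema).
#' @param path CSV file path.
#' @return `write_birth_records()` returns `path` invisibly;
#'   `read_birth_records()` returns the records.
#' @export
write_birth_records <- function(records, path) {
  need <- birth_record_dictionary()$column
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    schema_stop("records lack required column(s): ",
                paste(missing_cols, collapse = ", "))
  }
  records <- records[, need]
  records$date <- format(as.Date(records$date), "%Y-%m-%d")
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE, na = "")
  jsonlite::write_json(birth_record_dictionary(),
                       paste0(path, ".dict.json"), pretty = TRUE)
  invisible(path)
}

#' @rdname write_birth_records
#' @export
read_birth_records <- function(path) {
  dict <- birth_record_dictionary()
  header <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  extra <- setdiff(header, dict$column)
  missing_cols <- setdiff(dict$column, header)
  if (length(extra) || length(missing_cols)) {
    schema_stop(
      if (length(missing_cols)) paste0("missing column(s): ",
                                       paste(missing_cols, collapse = ", "), ". "),
      if (length(extra)) paste0("unknown column(s): ",
                                paste(extra, collapse = ", ")))
  }
  colclass <- c(integer = "integer", numeric = "numeric",
                character = "character", date = "character")[dict$type]
  df <- utils::read.csv(path, colClasses = unname(colclass),
                        check.names = FALSE)
  df$date <- as.Date(df$date)
  for (col in c("augmentation", "arm", "episiotomy", "operative_vaginal")) {
    df[[col]] <- as.integer(df[[col]])
  }
  df
}
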
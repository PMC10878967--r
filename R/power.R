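#' Closed-form power for a cross-sectional stepped wedge
#'
#' Computes the power to detect a difference in proportions in a
#' cross-sectional stepped-wedge design by generalized least squares on
#' cluster-period means under the nested-exchangeable correlation model.
#' Each cluster contributes a `T x T` covariance block with diagonal
#' `sigma2 * (1 + (m_eff - 1) * rho) / m_eff` and off-diagonal
#' `sigma2 * rho * r`, where `sigma2 = pbar * (1 - pbar)` at the midpoint of
#' the two proportions, `rho` is the within-period ICC and `rho * r` the
#' between-period within-cluster correlation. Unequal cluster-period sizes
#' (coefficient of variation `cv`) degrade information through the
#' effective size `m_eff = m / (1 + cv^2)`, the standard relative-efficiency
#' adjustment; periods shorter than the nominal period length (a truncated
#' final period) recruit proportionally fewer women. The treatment-effect
#' variance comes from the design matrix with period fixed effects, and
#' power uses the two-sided normal approximation
#' `Phi(|p0 - p1| / SE - z_{1-alpha/2})`.
#'
#' @param p_control,p_intervention outcome proportions under control and
#'   intervention, strictly inside (0, 1).
#' @param icc within-period intraclass correlation `rho`, in `[0, 1)`.
#' @param cac cluster autocorrelation `r`, in `[0, 1]`; the between-period
#'   correlation is `rho * r`.
#' @param mean_cluster_period_size mean women per cluster per full-length
#'   period contributing to the analyzed outcome.
#' @param cv_cluster_size coefficient of variation of cluster-period size.
#' @param alpha two-sided significance level.
#' @param design an [sw_design()]; the default four-cluster wedge.
#' @return Power in (0, 1), with the standard error of the treatment effect
#'   attached as `attr(, "se")`.
#' @examples
#' power_closed_form(0.40, 0.30, icc = 0.02, cac = 0.90,
#'                   mean_cluster_period_size = 300, cv_cluster_size = 0.60)
#' @seealso [power_by_simulation()]
#' @references Hussey MA, Hughes JP. Design and analysis of stepped wedge
#'   cluster randomized trials. Contemp Clin Trials 2007;28:182-191.
#'   Hooper R, Teerenstra S, de Hoop E, Eldridge S. Sample size calculation
#'   for stepped wedge and other longitudinal cluster randomised trials.
#'   Stat Med 2016;35:4718-4728.
#' @export
power_closed_form <- function(p_control, p_intervention, icc, cac,
                              mean_cluster_period_size, cv_cluster_size = 0,
                              alpha = 0.05, design = default_trial_design()) {
  stopifnot(inherits(design, "sw_design"))
  if (p_control <= 0 || p_control >= 1 || p_intervention <= 0 ||
      p_intervention >= 1) {
    stop("proportions must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (icc < 0 || icc >= 1 || cac < 0) {
    stop("need icc in [0, 1) and cac >= 0", call. = FALSE)
  }
  if (cac > 1) {
    stop("invalid correlation: between-period correlation icc * cac would ",
         "exceed the within-period icc", call. = FALSE)
  }
  stopifnot(mean_cluster_period_size > 0, cv_cluster_size >= 0,
            alpha > 0, alpha < 1)
  K <- design$n_clusters
  T <- design$n_periods
  pbar <- (p_control + p_intervention) / 2
  sig2 <- pbar * (1 - pbar)
  wts <- design$period_days / design$period_length_days
  m_eff <- mean_cluster_period_size * wts / (1 + cv_cluster_size^2)
  Vb <- matrix(sig2 * icc * cac, T, T)
  diag(Vb) <- sig2 * (1 + (m_eff - 1) * icc) / m_eff
  Vbi <- tryCatch(solve(Vb), error = function(e) {
    stop("design infeasible: singular cluster-period covariance", call. = FALSE)
  })
  info <- matrix(0, T + 1, T + 1)
  for (k in seq_len(K)) {
    Xk <- cbind(diag(T), as.numeric(seq_len(T) > design$sequence[k]))
    info <- info + t(Xk) %*% Vbi %*% Xk
  }
  var_beta <- tryCatch(solve(info)[T + 1, T + 1], error = function(e) {
    stop("design infeasible: singular GLS system (no within-period contrast)",
         call. = FALSE)
  })
  if (var_beta <= 0) stop("design infeasible: non-positive effect variance",
                          call. = FALSE)
  se <- sqrt(var_beta)
  pw <- stats::pnorm(abs(p_control - p_intervention) / se -
                       stats::qnorm(1 - alpha / 2))
  attr(pw, "se") <- se
  pw
}

#' Simulation-based power for a stepped wedge
#'
#' Estimates power by generating full individual-level trials with
#' [generate_trial()] — a Robson Group 1 population of the requested mean
#' cluster-period size and size CV, with the latent correlation structure
#' calibrated to the requested ICC and CAC — and analyzing each exactly as
#' the trial would: modified-Poisson GEE with exchangeable working
#' correlation on the non-transition records.
#'
#' The primary estimate `power` is the *information-based* power: the
#' two-sided z power implied by the mean and standard deviation of the
#' treatment-effect estimates across replicates. This is the quantity
#' [power_closed_form()] predicts — both describe the sampling distribution
#' of the effect estimate under a known variance. With very few clusters no
#' variance *estimator* concentrates around that sampling variance, so the
#' realized rejection fractions of the tests a trial could actually run are
#' reported alongside and can differ from the design power substantially:
#' `power_md_t` (Mancl-DeRouen variance, t(N-2) reference — the trial's
#' conservative analysis rule), `power_md_z`, `power_sandwich_z` (the
#' uncorrected sandwich, anti-conservative at four clusters) and
#' `power_model_z` (model-based working covariance).
#'
#' @param p_control,p_intervention,icc,cac,mean_cluster_period_size,cv_cluster_size,alpha,design
#'   as in [power_closed_form()].
#' @param n_sims number of simulated trials (at least 100).
#' @param seed integer seed; per-trial generator seeds are derived from it.
#' @return List with `power` and its delta-method 95% `mc_ci`; rejection
#'   fractions `power_md_t` (with exact binomial `mc_ci_md_t`),
#'   `power_md_z`, `power_sandwich_z`, `power_model_z`; `mean_log_rr` and
#'   `sd_log_rr`; `n_sims`; `n_failed` (non-converged fits, excluded from
#'   the estimate moments and counted as non-rejections). More than 10%
#'   failures triggers a warning recorded in `warning_failures`.
#' @export
power_by_simulation <- function(p_control, p_intervention, icc, cac,
                                mean_cluster_period_size, cv_cluster_size = 0,
                                alpha = 0.05, design = default_trial_design(),
                                n_sims = 1000, seed = 1) {
  if (n_sims < 100) stop("need n_sims >= 100", call. = FALSE)
  rr <- p_intervention / p_control
  set.seed(as.integer(seed))
  sim_seeds <- sample.int(2^31 - 2, n_sims)
  zcrit <- stats::qnorm(1 - alpha / 2)
  tcrit <- stats::qt(1 - alpha / 2, design$n_clusters - 2)
  est <- rep(NA_real_, n_sims)
  rej_md_z <- rej_md_t <- rej_sw <- rej_mb <- logical(n_sims)
  failed <- 0L
  for (b in seq_len(n_sims)) {
    cfg <- generator_config(
      design = design,
      mean_cluster_period_size = mean_cluster_period_size,
      cv_cluster_size = cv_cluster_size,
      p_nulliparous = 1, p_onset = c(spontaneous = 1, induced = 0,
                                     prelabor_cesarean = 0),
      p_presentation = c(cephalic = 1, breech = 0, transverse_oblique = 0),
      p_multiple = 0, ga_term_mean = 39, ga_term_sd = 0.8, p_early = 0,
      cs_baseline = stats::setNames(rep(p_control, 10), as.character(1:10)),
      cesarean_rr = rr, icc = icc, cac = cac, seed = sim_seeds[b])
    d <- generate_trial(cfg)
    d <- d[d$robson_group == 1L & d$condition != "transition", , drop = FALSE]
    d$treatment <- as.integer(d$condition == "intervention")
    res <- tryCatch({
      fit <- suppressWarnings(gee_mp(d, outcome = "cesarean"))
      if (!fit$converged) NULL else {
        vmd <- sandwich_variance(fit, "mancl_derouen")$matrix["treatment", "treatment"]
        vsw <- sandwich_variance(fit, "sandwich")$matrix["treatment", "treatment"]
        vmb <- sandwich_variance(fit, "model_based")$matrix["treatment", "treatment"]
        c(est = fit$beta[["treatment"]], se_md = sqrt(vmd),
          se_sw = sqrt(vsw), se_mb = sqrt(vmb))
      }
    }, error = function(e) NULL)
    if (is.null(res)) {
      failed <- failed + 1L
    } else {
      est[b] <- res[["est"]]
      rej_md_z[b] <- abs(res[["est"]] / res[["se_md"]]) > zcrit
      rej_md_t[b] <- abs(res[["est"]] / res[["se_md"]]) > tcrit
      rej_sw[b] <- abs(res[["est"]] / res[["se_sw"]]) > zcrit
      rej_mb[b] <- abs(res[["est"]] / res[["se_mb"]]) > zcrit
    }
  }
  ok <- est[!is.na(est)]
  n_ok <- length(ok)
  m_hat <- mean(ok)
  s_hat <- stats::sd(ok)
  x <- abs(m_hat) / s_hat
  power_info <- stats::pnorm(x - zcrit)
  # delta-method MC interval: Var(x_hat) ~ (1 + x^2/2) / n
  se_x <- sqrt((1 + x^2 / 2) / n_ok)
  se_pw <- stats::dnorm(x - zcrit) * se_x
  hits_t <- sum(rej_md_t)
  out <- list(power = power_info,
              mc_ci = c(max(0, power_info - 1.96 * se_pw),
                        min(1, power_info + 1.96 * se_pw)),
              power_md_t = hits_t / n_sims,
              mc_ci_md_t = as.numeric(stats::binom.test(hits_t, n_sims)$conf.int),
              power_md_z = mean(rej_md_z),
              power_sandwich_z = mean(rej_sw),
              power_model_z = mean(rej_mb),
              mean_log_rr = m_hat, sd_log_rr = s_hat,
              n_sims = n_sims, n_failed = failed,
              warning_failures = failed > 0.1 * n_sims)
  if (out$warning_failures) {
    warning("more than 10% of simulated fits failed to converge",
            call. = FALSE)
  }
  out
}
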
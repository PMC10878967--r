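#' Crude rate as a percentage
#'
#' `100 * numerator / denominator`, half-up rounded to one decimal — the
#' crude (unadjusted) rate as printed in trial tables.
#'
#' @param numerator,denominator non-negative counts with
#'   `numerator <= denominator`, `denominator > 0`.
#' @return Percentage to one decimal.
#' @examples
#' crude_rate(1709, 4302)
#' @export
crude_rate <- function(numerator, denominator) {
  stopifnot(all(denominator > 0), all(numerator >= 0),
            all(numerator <= denominator))
  round_half_up(100 * numerator / denominator, 1)
}

#' Crude absolute difference in percentage points
#'
#' Intervention-period rate minus control-period rate, one decimal.
#'
#' @param rate_intervention,rate_control percentages in `[0, 100]`.
#' @return Difference in percentage points, one decimal.
#' @examples
#' crude_absolute_difference(39.7, 45.2)
#' @export
crude_absolute_difference <- function(rate_intervention, rate_control) {
  stopifnot(all(rate_intervention >= 0 & rate_intervention <= 100),
            all(rate_control >= 0 & rate_control <= 100))
  round_half_up(rate_intervention - rate_control, 1)
}

#' Define a trial outcome
#'
#' An outcome specification binds a name to a numerator column, a
#' denominator rule (a predicate selecting the records it is defined on —
#' all women, a Robson subset, women in spontaneous labor, vaginal births,
#' the survey subsample), an analysis unit (women or babies), and an
#' estimand (relative risk, or mean difference for durations).
#'
#' @param name outcome label.
#' @param numerator column holding the binary outcome (for `"rr"`) or the
#'   duration in days (for `"mean_difference"`); for `unit = "babies"` a
#'   per-woman count column paired with `n_babies`.
#' @param denominator function of the analysis data frame returning a
#'   logical row mask; default: all women.
#' @param estimand `"rr"` or `"mean_difference"`.
#' @param unit `"women"` or `"babies"` (per-baby rows are expanded from the
#'   per-woman counts before fitting).
#' @return An object of class `"outcome_spec"`.
#' @export
outcome_spec <- function(name, numerator, denominator = function(df) rep(TRUE, nrow(df)),
                         estimand = c("rr", "mean_difference"),
                         unit = c("women", "babies")) {
  structure(list(name = name, numerator = numerator,
                 denominator = denominator,
                 estimand = match.arg(estimand), unit = match.arg(unit)),
            class = "outcome_spec")
}

#' Default outcome set for the analysis pipeline
#'
#' The primary outcome (cesarean in Robson Group 1), process-of-care
#' outcomes with their denominator hierarchy (Robson subsets; augmentation
#' and artificial rupture of membranes among spontaneous labor; episiotomy
#' and operative vaginal birth among vaginal births), duration outcomes as
#' mean differences, and per-baby health outcomes.
#'
#' @return List of [outcome_spec()] objects.
#' @export
default_outcome_specs <- function() {
  rg <- function(...) { gs <- c(...); function(df) df$robson_group %in% gs }
  spont <- function(df) df$labor_onset == "spontaneous"
  vaginal <- function(df) df$cesarean == 0
  list(
    outcome_spec("cesarean_robson1", "cesarean", rg(1)),
    outcome_spec("cesarean_robson1_3", "cesarean", rg(1, 3)),
    outcome_spec("cesarean_robson1_5", "cesarean", rg(1:5)),
    outcome_spec("cesarean_all", "cesarean"),
    outcome_spec("augmentation", "augmentation", spont),
    outcome_spec("arm", "arm", spont),
    outcome_spec("episiotomy", "episiotomy", vaginal),
    outcome_spec("operative_vaginal", "operative_vaginal", vaginal),
    outcome_spec("days_admission_to_birth", "days_admission_to_birth",
                 estimand = "mean_difference"),
    outcome_spec("days_birth_to_discharge", "days_birth_to_discharge",
                 estimand = "mean_difference"),
    outcome_spec("stillbirth", "n_stillbirths", unit = "babies"),
    outcome_spec("neonatal_death", "n_neonatal_deaths", unit = "babies")
  )
}

#' Postpartum-survey subsample rule
#'
#' Women in Robson Group 1 or 3 with at least one liveborn baby who carry
#' the survey flag (births in the closing days of each period).
#'
#' @param df analysis data frame.
#' @return Logical row mask.
#' @export
survey_subsample <- function(df) {
  df$robson_group %in% c(1L, 3L) &
    (df$n_babies - df$n_stillbirths) >= 1L & df$surveyed == 1L
}

# expand per-woman baby counts into per-baby binary rows
expand_babies <- function(df, count_col) {
  nb <- df$n_babies
  out <- df[rep(seq_len(nrow(df)), nb), , drop = FALSE]
  # first `count` babies of each woman carry the event
  baby_idx <- sequence(nb)
  out$baby_event <- as.integer(baby_idx <= rep(df[[count_col]], nb))
  out
}

#' Per-cluster, per-condition flow counts
#'
#' Counts of women and babies by cluster and planned condition (control,
#' transition, intervention) — the trial-diagram numbers. Conditions are
#' derived from the design schedule and the birth date, so the counts
#' partition the dataset and the analysis N is the control plus intervention
#' total.
#'
#' @param data birth records with `cluster`, `date` and `n_babies`.
#' @param design an [sw_design()].
#' @return Data frame with `cluster`, `condition`, `n_women`, `n_babies`,
#'   plus attribute `totals` (named list incl. `n_analysis_women`).
#' @export
flow_counts <- function(data, design) {
  data <- as.data.frame(data)
  cond <- factor(sw_condition(design, data$cluster, data$date),
                 levels = c("control", "transition", "intervention"))
  cl <- factor(data$cluster, levels = seq_len(design$n_clusters))
  nb <- if ("n_babies" %in% names(data)) data$n_babies else rep(1L, nrow(data))
  women <- as.data.frame(table(cluster = cl, condition = cond),
                         responseName = "n_women")
  babies <- stats::aggregate(nb, list(cluster = cl, condition = cond), sum,
                             drop = FALSE)
  babies$x[is.na(babies$x)] <- 0
  out <- merge(women, babies, by = c("cluster", "condition"), sort = TRUE)
  names(out)[names(out) == "x"] <- "n_babies"
  out$cluster <- as.integer(as.character(out$cluster))
  out <- out[order(out$cluster, out$condition), ]
  rownames(out) <- NULL
  tot <- tapply(out$n_women, out$condition, sum)
  attr(out, "totals") <- list(
    n_women = sum(out$n_women), n_babies = sum(out$n_babies),
    n_control_women = unname(tot["control"]),
    n_transition_women = unname(tot["transition"]),
    n_intervention_women = unname(tot["intervention"]),
    n_analysis_women = unname(tot["control"] + tot["intervention"]))
  out
}

#' Run the full stepped-wedge trial analysis
#'
#' The intention-to-treat pipeline: assigns each woman her *planned*
#' condition from the design schedule and her birth date (a recorded
#' `condition` column is only cross-checked, never used), excludes
#' transition-window births from estimation while reporting their count,
#' evaluates every outcome specification — crude rates by arm, crude
#' absolute difference, and a relative risk from the modified-Poisson GEE
#' with Mancl-DeRouen variance and t(N-2) inference, or a mean difference
#' for durations — computes the trial-flow counts, and estimates the ICC of
#' the primary outcome from the control period. A model that fails to
#' converge yields a row with crude statistics and an explicit
#' `"no estimate"` marker; the run completes.
#'
#' @param data birth records (schema of [generate_trial()] /
#'   [read_birth_records()]).
#' @param design an [sw_design()].
#' @param outcomes list of [outcome_spec()]s.
#' @param icc_outcome outcome for the control-period ICC report.
#' @param icc_boot cluster-bootstrap resamples for the ICC interval (kept
#'   moderate here; [estimate_icc()] defaults to 2,000 when called
#'   directly).
#' @param seed seed for the ICC bootstrap.
#' @return Object of class `"results_bundle"`: `results` (one row per
#'   outcome), `flow`, `icc`, `exclusions`, `n_analysis`. Serialize with
#'   [results_json()].
#' @export
run_trial_analysis <- function(data, design, outcomes = default_outcome_specs(),
                               icc_outcome = "cesarean", icc_boot = 200,
                               seed = 1) {
  data <- as.data.frame(data)
  need <- c("cluster", "date", "robson_group", "cesarean")
  miss <- setdiff(need, names(data))
  if (length(miss)) schema_stop("analysis needs column(s): ",
                                paste(miss, collapse = ", "))
  planned <- sw_condition(design, data$cluster, data$date)
  n_cond_mismatch <- 0L
  if ("condition" %in% names(data)) {
    n_cond_mismatch <- sum(planned != data$condition, na.rm = TRUE)
    if (n_cond_mismatch > 0) {
      warning(n_cond_mismatch, " recorded condition value(s) disagree with ",
              "the planned schedule; planned exposure is used", call. = FALSE)
    }
  }
  data$condition <- planned
  data$period <- sw_period(design, data$date)
  flow <- flow_counts(data, design)

  ana <- data[data$condition != "transition", , drop = FALSE]
  ana$treatment <- as.integer(ana$condition == "intervention")
  n_transition <- nrow(data) - nrow(ana)

  rows <- lapply(outcomes, function(sp) {
    den <- sp$denominator(ana)
    den[is.na(den)] <- FALSE
    sub <- ana[den, , drop = FALSE]
    base <- data.frame(outcome = sp$name, estimand = sp$estimand,
                       unit = sp$unit, stringsAsFactors = FALSE)
    if (sp$unit == "babies") {
      sub <- expand_babies(sub, sp$numerator)
      ycol <- "baby_event"
    } else {
      ycol <- sp$numerator
    }
    for (arm in c(0, 1)) {
      part <- sub[sub$treatment == arm, , drop = FALSE]
      yv <- part[[ycol]]
      lab <- if (arm == 1) "int" else "ctl"
      if (sp$estimand == "rr") {
        yv <- yv[!is.na(yv)]
        base[[paste0("n_", lab)]] <- sum(yv)
        base[[paste0("N_", lab)]] <- length(yv)
        base[[paste0("pct_", lab)]] <-
          if (length(yv)) 100 * mean(yv) else NA_real_
      } else {
        base[[paste0("mean_", lab)]] <- mean(yv, na.rm = TRUE)
        base[[paste0("sd_", lab)]] <- stats::sd(yv, na.rm = TRUE)
        base[[paste0("N_", lab)]] <- sum(!is.na(yv))
      }
    }
    if (sp$estimand == "rr") {
      base$crude_diff <- base$pct_int - base$pct_ctl
      est <- tryCatch({
        fit <- gee_mp(sub, outcome = ycol)
        if (!fit$converged) stop("no convergence")
        effect_estimate(fit, sandwich_variance(fit, "mancl_derouen"))
      }, error = function(e) NULL, warning = function(w) NULL)
      if (is.null(est)) {
        base$estimate <- NA_real_; base$ci_low <- NA_real_
        base$ci_high <- NA_real_; base$p_value <- NA_real_
        base$df <- NA_integer_; base$note <- "no estimate (model did not converge)"
      } else {
        base$estimate <- est$rr; base$ci_low <- est$ci_low
        base$ci_high <- est$ci_high; base$p_value <- est$p_value
        base$df <- est$df; base$note <- ""
      }
    } else {
      base$crude_diff <- base$mean_int - base$mean_ctl
      md <- tryCatch(mean_difference(sub, outcome = ycol),
                     error = function(e) NULL)
      if (is.null(md)) {
        base$estimate <- NA_real_; base$ci_low <- NA_real_
        base$ci_high <- NA_real_; base$p_value <- NA_real_
        base$df <- NA_integer_; base$note <- "no estimate (model did not converge)"
      } else {
        base$estimate <- md$difference; base$ci_low <- md$ci_low
        base$ci_high <- md$ci_high; base$p_value <- md$p_value
        base$df <- md$df; base$note <- ""
      }
    }
    base
  })
  rr_rows <- Filter(function(r) r$estimand == "rr", rows)
  md_rows <- Filter(function(r) r$estimand == "mean_difference", rows)
  results <- list(ratios = do.call(rbind, rr_rows),
                  differences = do.call(rbind, md_rows))

  icc_rep <- tryCatch(
    estimate_icc(ana[ana$condition == "control", , drop = FALSE],
                 outcome = icc_outcome, n_boot = icc_boot, seed = seed),
    error = function(e) list(icc = NA_real_, ci_low = NA_real_,
                             ci_high = NA_real_, error = conditionMessage(e)))
  icc_rep$fit <- NULL

  structure(list(
    results = results, flow = flow, icc = icc_rep,
    exclusions = list(n_transition = n_transition,
                      n_condition_mismatch = n_cond_mismatch),
    n_analysis = nrow(ana), design = design),
    class = "results_bundle")
}

#' @export
print.results_bundle <- function(x, ...) {
  tot <- attr(x$flow, "totals")
  cat(sprintf("Stepped-wedge trial analysis: %d women analyzed (%d control, %d intervention); %d transition births excluded\n",
              x$n_analysis, tot$n_control_women, tot$n_intervention_women,
              x$exclusions$n_transition))
  r <- x$results$ratios
  cat("\nRelative-risk outcomes (Mancl-DeRouen, t(N-2)):\n")
  disp <- data.frame(
    outcome = r$outcome,
    intervention = sprintf("%d/%d (%.1f)", r$n_int, r$N_int, r$pct_int),
    control = sprintf("%d/%d (%.1f)", r$n_ctl, r$N_ctl, r$pct_ctl),
    crude_diff = round_half_up(r$crude_diff, 1),
    RR = ifelse(is.na(r$estimate), "-",
                sprintf("%.2f (%.2f-%.2f)", r$estimate, r$ci_low, r$ci_high)))
  print(disp, row.names = FALSE)
  if (any(r$note != "")) {
    for (i in which(r$note != "")) cat("  note [", r$outcome[i], "]: ",
                                       r$note[i], "\n", sep = "")
  }
  m <- x$results$differences
  if (!is.null(m) && nrow(m)) {
    cat("\nDuration outcomes (days; mean difference, Gaussian GEE CI):\n")
    dd <- data.frame(outcome = m$outcome,
                     intervention = sprintf("%.2f (%.2f)", m$mean_int, m$sd_int),
                     control = sprintf("%.2f (%.2f)", m$mean_ctl, m$sd_ctl),
                     difference = ifelse(is.na(m$estimate), "-",
                                         sprintf("%.2f (%.2f-%.2f)", m$estimate,
                                                 m$ci_low, m$ci_high)))
    print(dd, row.names = FALSE)
  }
  if (!is.na(x$icc$icc)) {
    cat(sprintf("\nControl-period ICC (primary outcome): %.3f (95%% CI %.3f; %.3f)\n",
                x$icc$icc, x$icc$ci_low, x$icc$ci_high))
  }
  invisible(x)
}

#' Serialize a results bundle to JSON
#'
#' @param bundle a [run_trial_analysis()] result.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when written to a file).
#' @export
results_json <- function(bundle, path = NULL) {
  stopifnot(inherits(bundle, "results_bundle"))
  tot <- attr(bundle$flow, "totals")
  payload <- list(
    n_analysis = bundle$n_analysis,
    exclusions = bundle$exclusions,
    flow = bundle$flow,
    flow_totals = tot,
    ratio_outcomes = bundle$results$ratios,
    difference_outcomes = bundle$results$differences,
    icc = bundle$icc[c("icc", "ci_low", "ci_high")])
  js <- jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
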
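#' Stepped-wedge design objects
#'
#' `sw_design()` encodes the geometry of a cross-sectional stepped-wedge
#' cluster-randomized trial: every cluster starts in the control condition,
#' crosses over to the intervention at the end of its assigned step, and a
#' short transition window after each crossover is excluded from analysis
#' while the intervention beds in.
#'
#' Analysis periods are consecutive blocks of `period_length_days` days
#' starting at `start_date`; the final period is truncated at `end_date`
#' when the trial calendar does not divide evenly. The cluster assigned to
#' step `k` is in the control condition throughout periods `1..k`, in
#' transition for the first `transition_days` days of period `k + 1`, and in
#' the intervention condition afterwards.
#'
#' @param n_clusters number of clusters (hospitals); at least 2.
#' @param n_periods number of analysis periods.
#' @param period_length_days length of one analysis period, in days.
#' @param transition_days length of the post-crossover transition window
#'   excluded from analysis, in days (0 disables it).
#' @param sequence integer vector mapping cluster id to step index in
#'   `1..n_clusters`; a permutation. Defaults to the identity permutation
#'   (cluster k crosses at step k); use [randomize_sequences()] for a
#'   randomized assignment.
#' @param start_date first day of the trial (`Date` or `"YYYY-MM-DD"`).
#' @param end_date last day of the trial; `NULL` (default) means
#'   `n_periods` full periods, values beyond the last period are clamped.
#'   See [default_trial_design()] for the truncated-final-period geometry
#'   the package uses as its reference design.
#'
#' @return An object of class `"sw_design"`: a list with the fields above
#'   plus `period_start` / `period_end` (Date vectors) and
#'   `period_days` (length of each period after truncation).
#' @examples
#' d <- sw_design(4)
#' exposure_matrix(d)
#' @seealso [randomize_sequences()], [exposure_matrix()], [sw_condition()]
#' @export
sw_design <- function(n_clusters = 4, n_periods = 7, period_length_days = 61,
                      transition_days = 14, sequence = seq_len(n_clusters),
                      start_date = "2021-07-01", end_date = NULL) {
  if (n_clusters < 2) {
    stop("design infeasible: a stepped wedge needs at least 2 clusters",
         call. = FALSE)
  }
  if (n_periods < n_clusters + 1) {
    stop("design infeasible: need at least n_clusters + 1 periods so every ",
         "cluster contributes both control and intervention time", call. = FALSE)
  }
  if (transition_days < 0 || period_length_days < 1) {
    stop("period_length_days must be positive and transition_days non-negative",
         call. = FALSE)
  }
  if (transition_days >= period_length_days) {
    stop("transition window must be shorter than an analysis period",
         call. = FALSE)
  }
  if (length(sequence) != n_clusters || !setequal(sequence, seq_len(n_clusters))) {
    stop("sequence must be a permutation of 1..n_clusters", call. = FALSE)
  }
  start_date <- as.Date(start_date)
  if (is.null(end_date)) {
    end_date <- start_date + n_periods * period_length_days - 1L
  }
  end_date <- min(as.Date(end_date),
                  start_date + n_periods * period_length_days - 1L)
  period_start <- start_date + (seq_len(n_periods) - 1L) * period_length_days
  period_end <- pmin(period_start + period_length_days - 1L, end_date)
  if (any(period_start > end_date)) {
    stop("design infeasible: trial ends before all periods begin", call. = FALSE)
  }
  structure(
    list(n_clusters = as.integer(n_clusters),
         n_periods = as.integer(n_periods),
         period_length_days = as.integer(period_length_days),
         transition_days = as.integer(transition_days),
         sequence = as.integer(sequence),
         start_date = start_date, end_date = end_date,
         period_start = period_start, period_end = period_end,
         period_days = as.integer(period_end - period_start + 1L)),
    class = "sw_design")
}

#' Reference four-hospital stepped-wedge geometry
#'
#' The package's default trial geometry: four clusters, seven 61-day
#' (two-month) analysis periods starting 1 July 2021, one cluster crossing
#' over per step with a 14-day transition window, and the trial ending
#' 15 July 2022 so the seventh period is truncated to 14 days. Used as the
#' default design by the power functions and the synthetic-data generator.
#'
#' @param sequence optional cluster-to-step permutation (see [sw_design()]).
#' @return An [sw_design()] object.
#' @export
default_trial_design <- function(sequence = 1:4) {
  sw_design(4, sequence = sequence, end_date = "2022-07-15")
}

#' @export
print.sw_design <- function(x, ...) {
  cat(sprintf("Stepped-wedge design: %d clusters, %d periods of %d days (%s to %s)\n",
              x$n_clusters, x$n_periods, x$period_length_days,
              format(x$start_date), format(x$end_date)))
  cat(sprintf("Transition window: %d days after each crossover\n", x$transition_days))
  cat("Sequence (cluster -> step):",
      paste(sprintf("%d->%d", seq_len(x$n_clusters), x$sequence), collapse = ", "),
      "\n")
  invisible(x)
}

#' Randomly assign clusters to stepped-wedge sequences
#'
#' Draws a uniformly random permutation of clusters onto crossover steps,
#' reproducible from `seed`. The assignment is recorded in an audit log
#' attached to the returned design (`attr(, "audit")`), mirroring the
#' concealed computer-generated allocation list a trial statistician keeps.
#'
#' @param n_clusters number of clusters; at least 2.
#' @param seed integer seed; identical seeds reproduce identical assignments.
#' @param ... further arguments passed to [sw_design()].
#' @return An `"sw_design"` whose `sequence` is the random assignment.
#' @examples
#' randomize_sequences(4, seed = 20210701)$sequence
#' @export
randomize_sequences <- function(n_clusters, seed, ...) {
  if (n_clusters < 2) {
    stop("design infeasible: a stepped wedge needs at least 2 clusters",
         call. = FALSE)
  }
  stopifnot(is.numeric(seed), length(seed) == 1)
  perm <- local({
    set.seed(as.integer(seed))
    sample.int(n_clusters)
  })
  des <- sw_design(n_clusters = n_clusters, sequence = perm, ...)
  attr(des, "audit") <- data.frame(
    cluster = seq_len(n_clusters), step = perm, seed = as.integer(seed),
    assigned = format(Sys.time(), "%Y-%m-%d %H:%M:%S", tz = "UTC"))
  des
}

#' Cluster-by-period exposure matrix
#'
#' Returns the planned exposure of each cluster in each analysis period:
#' `0` (control) before the cluster's step, `1` (intervention) after.
#' When `mark_transition = TRUE` the first period after a cluster's
#' crossover is marked `"excluded"` in a character matrix, reflecting the
#' transition window carved out of it; numeric exposure is unaffected
#' because transition *records* (not whole periods) are excluded by the
#' analysis pipeline.
#'
#' @param design an [sw_design()] object.
#' @param mark_transition mark post-crossover transition periods.
#' @return A `n_clusters x n_periods` matrix (numeric, or character when
#'   `mark_transition = TRUE`).
#' @examples
#' exposure_matrix(sw_design(4))
#' @export
exposure_matrix <- function(design, mark_transition = FALSE) {
  stopifnot(inherits(design, "sw_design"))
  K <- design$n_clusters; T <- design$n_periods
  X <- matrix(0, K, T, dimnames = list(cluster = seq_len(K), period = seq_len(T)))
  for (k in seq_len(K)) X[k, seq_len(T) > design$sequence[k]] <- 1
  if (!mark_transition || design$transition_days == 0L) return(X)
  Xc <- matrix(as.character(X), K, T, dimnames = dimnames(X))
  for (k in seq_len(K)) {
    first_int <- design$sequence[k] + 1L
    if (first_int <= T) Xc[k, first_int] <- "excluded"
  }
  Xc
}

#' Planned condition of a cluster on a given date
#'
#' Intention-to-treat condition by planned exposure: derived from the
#' randomization schedule and the calendar date alone.
#'
#' @param design an [sw_design()] object.
#' @param cluster integer cluster id(s).
#' @param date `Date` (or coercible) vector, recycled against `cluster`.
#' @return Character vector in `c("control", "transition", "intervention")`.
#' @examples
#' d <- sw_design(4)
#' sw_condition(d, 1, c("2021-07-15", "2021-09-05", "2021-10-01"))
#' @export
sw_condition <- function(design, cluster, date) {
  stopifnot(inherits(design, "sw_design"))
  date <- as.Date(date)
  n <- max(length(cluster), length(date))
  cluster <- rep_len(as.integer(cluster), n)
  date <- rep_len(date, n)
  if (any(cluster < 1L | cluster > design$n_clusters, na.rm = TRUE)) {
    stop("unknown cluster id", call. = FALSE)
  }
  if (any(date < design$start_date | date > design$end_date, na.rm = TRUE)) {
    stop("date outside the trial range ", format(design$start_date), "..",
         format(design$end_date), call. = FALSE)
  }
  step <- design$sequence[cluster]
  crossover <- design$period_start[pmin(step + 1L, design$n_periods)]
  crossover[step + 1L > design$n_periods] <- design$end_date + 1L  # never crosses (defensive)
  out <- ifelse(date < crossover, "control",
                ifelse(date < crossover + design$transition_days,
                       "transition", "intervention"))
  out
}

#' Analysis period containing a date
#'
#' @param design an [sw_design()] object.
#' @param date `Date` (or coercible) vector.
#' @return Integer period index in `1..n_periods`.
#' @export
sw_period <- function(design, date) {
  stopifnot(inherits(design, "sw_design"))
  date <- as.Date(date)
  if (any(date < design$start_date | date > design$end_date, na.rm = TRUE)) {
    stop("date outside the trial range", call. = FALSE)
  }
  findInterval(as.numeric(date), as.numeric(design$period_start))
}
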
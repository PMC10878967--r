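#' Robson ten-group classification of births
#'
#' Classifies every woman into exactly one of the ten mutually exclusive,
#' all-inclusive Robson groups on the basis of parity, previous cesarean,
#' onset of labor, fetal presentation and lie, number of fetuses, and
#' gestational age (term or preterm). The hierarchy follows the WHO
#' implementation manual for the (non-subdivided) ten-group system:
#'
#' 1. multiple pregnancy -> Group 8 (regardless of anything else);
#' 2. singleton transverse or oblique lie -> Group 9 (incl. previous CS);
#' 3. singleton breech -> Group 6 if nulliparous, Group 7 if multiparous
#'    (Group 7 includes women with a previous cesarean);
#' 4. singleton cephalic preterm -> Group 10 (incl. previous cesarean);
#' 5. singleton cephalic term with at least one previous cesarean -> Group 5;
#' 6. remaining nulliparous -> Group 1 if labor was spontaneous, else
#'    Group 2 (induced labor or prelabor cesarean);
#' 7. remaining multiparous -> Group 3 if spontaneous, else Group 4.
#'
#' @param profiles data frame with columns `parity` (previous births,
#'   integer >= 0), `previous_cs` (previous cesareans, integer >= 0, at most
#'   `parity`), `labor_onset` (one of `"spontaneous"`, `"induced"`,
#'   `"prelabor_cesarean"`), `presentation` (one of `"cephalic"`, `"breech"`,
#'   `"transverse_oblique"`), `n_fetuses` (integer >= 1) and
#'   `gestational_age_weeks` (numeric >= 20).
#' @param term_threshold_weeks completed weeks at or above which a pregnancy
#'   counts as term; 37 by WHO convention.
#' @param strict if `TRUE` (default) any invalid row is an error naming the
#'   offending field; if `FALSE`, invalid rows classify to `NA` and the
#'   number of rejected rows is attached as `attr(, "n_invalid")`.
#' @return Integer vector of group numbers 1-10 (with `NA` for invalid rows
#'   when `strict = FALSE`).
#' @examples
#' robson_classify(data.frame(
#'   parity = 0, previous_cs = 0, labor_onset = "spontaneous",
#'   presentation = "cephalic", n_fetuses = 1, gestational_age_weeks = 39))
#' @references Robson MS. Classification of caesarean sections.
#'   Fetal Matern Med Rev 2001;12:23-39. WHO. Robson classification:
#'   implementation manual. Geneva: World Health Organization; 2017.
#' @export
robson_classify <- function(profiles, term_threshold_weeks = 37, strict = TRUE) {
  profiles <- as.data.frame(profiles)
  required <- c("parity", "previous_cs", "labor_onset", "presentation",
                "n_fetuses", "gestational_age_weeks")
  missing_cols <- setdiff(required, names(profiles))
  if (length(missing_cols)) {
    stop("missing obstetric profile column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  onset <- as.character(profiles$labor_onset)
  pres <- as.character(profiles$presentation)
  bad <- list(
    parity = !is.finite(profiles$parity) | profiles$parity < 0,
    previous_cs = !is.finite(profiles$previous_cs) | profiles$previous_cs < 0 |
      profiles$previous_cs > profiles$parity,
    labor_onset = !onset %in% c("spontaneous", "induced", "prelabor_cesarean"),
    presentation = !pres %in% c("cephalic", "breech", "transverse_oblique"),
    n_fetuses = !is.finite(profiles$n_fetuses) | profiles$n_fetuses < 1,
    gestational_age_weeks = !is.finite(profiles$gestational_age_weeks) |
      profiles$gestational_age_weeks < 20
  )
  invalid <- Reduce(`|`, bad)
  invalid[is.na(invalid)] <- TRUE
  if (strict && any(invalid)) {
    fields <- names(bad)[vapply(bad, function(b) any(b, na.rm = TRUE), logical(1))]
    stop("invalid obstetric profile in field(s): ",
         paste(fields, collapse = ", "),
         " (", sum(invalid), " row(s))", call. = FALSE)
  }

  nullip <- profiles$parity == 0
  prev_cs <- profiles$previous_cs >= 1
  term <- profiles$gestational_age_weeks >= term_threshold_weeks
  spont <- onset == "spontaneous"

  g <- integer(nrow(profiles))
  g[] <- NA_integer_
  ok <- !invalid
  multiple <- profiles$n_fetuses >= 2
  g[ok & multiple] <- 8L
  rest <- ok & !multiple
  g[rest & pres == "transverse_oblique"] <- 9L
  breech <- rest & pres == "breech"
  g[breech & nullip] <- 6L
  g[breech & !nullip] <- 7L
  ceph <- rest & pres == "cephalic"
  g[ceph & !term] <- 10L
  ceph_term <- ceph & term
  g[ceph_term & prev_cs] <- 5L
  low <- ceph_term & !prev_cs
  g[low & nullip & spont] <- 1L
  g[low & nullip & !spont] <- 2L
  g[low & !nullip & spont] <- 3L
  g[low & !nullip & !spont] <- 4L
  if (!strict) attr(g, "n_invalid") <- sum(invalid)
  g
}

#' WHO-style Robson audit table
#'
#' Tabulates per-group counts, sizes, cesarean rates and contributions from
#' per-woman records: each woman is counted once (multiple births contribute
#' one row). Groups with no members appear with zero counts so tables are
#' comparable across months and hospitals.
#'
#' The WHO report columns satisfy three identities (up to rounding at
#' display time; stored values are full precision): group sizes sum to the
#' total N, absolute contributions sum to the overall cesarean rate, and
#' relative contributions sum to 100%.
#'
#' @param records data frame with a `cesarean` column (logical or 0/1) and
#'   either a precomputed `robson_group` column or the obstetric profile
#'   columns accepted by [robson_classify()].
#' @param term_threshold_weeks passed to [robson_classify()] when groups
#'   must be computed.
#' @return A data frame of class `"robson_table"` with one row per group:
#'   `group`, `n_women`, `n_cesarean`, `group_size_pct`, `group_cs_rate_pct`,
#'   `absolute_contribution_pct`, `relative_contribution_pct`; attributes
#'   `n_total`, `n_cesarean_total`, `overall_cs_rate_pct`.
#' @examples
#' rec <- data.frame(robson_group = c(1, 1, 2, 5), cesarean = c(0, 1, 1, 1))
#' robson_table(rec)
#' @export
robson_table <- function(records, term_threshold_weeks = 37) {
  records <- as.data.frame(records)
  if (nrow(records) == 0) stop("empty input: no birth records", call. = FALSE)
  if (!"cesarean" %in% names(records)) {
    stop("records must contain a 'cesarean' column", call. = FALSE)
  }
  if ("robson_group" %in% names(records)) {
    grp <- as.integer(records$robson_group)
    if (any(is.na(grp) | grp < 1 | grp > 10)) {
      stop("robson_group values must be integers in 1..10", call. = FALSE)
    }
  } else {
    grp <- robson_classify(records, term_threshold_weeks)
  }
  cs <- as.integer(as.logical(records$cesarean))
  if (anyNA(cs)) stop("cesarean flag contains missing values", call. = FALSE)
  n_total <- length(grp)
  cs_total <- sum(cs)
  gf <- factor(grp, levels = 1:10)
  n_women <- as.integer(table(gf))
  n_cesarean <- as.integer(tapply(cs, gf, sum, default = 0L))
  out <- data.frame(
    group = 1:10,
    n_women = n_women,
    n_cesarean = n_cesarean,
    group_size_pct = 100 * n_women / n_total,
    group_cs_rate_pct = ifelse(n_women > 0, 100 * n_cesarean / n_women, NA_real_),
    absolute_contribution_pct = 100 * n_cesarean / n_total,
    relative_contribution_pct = if (cs_total > 0) 100 * n_cesarean / cs_total else NA_real_
  )
  attr(out, "n_total") <- n_total
  attr(out, "n_cesarean_total") <- cs_total
  attr(out, "overall_cs_rate_pct") <- 100 * cs_total / n_total
  class(out) <- c("robson_table", "data.frame")
  out
}

#' @export
print.robson_table <- function(x, digits = 1, ...) {
  cat(sprintf("Robson classification table: %d women, %d cesareans (%.1f%%)\n",
              attr(x, "n_total"), attr(x, "n_cesarean_total"),
              attr(x, "overall_cs_rate_pct")))
  df <- as.data.frame(x)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], round_half_up, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Monthly Robson audit-and-feedback report
#'
#' Renders the Robson table for one calendar month plus the trailing trend
#' of the overall and Group-1 cesarean rates for every month up to and
#' including it — the table shared with a hospital at its monthly cesarean
#' audit meeting. A month with no births yields an explicit "no births"
#' report rather than an error. Records with invalid obstetric profiles are
#' excluded from the table and counted in the report footer.
#'
#' @param records data frame with a `date` column (`Date` or coercible),
#'   a `cesarean` column, and profile columns or `robson_group` as in
#'   [robson_table()].
#' @param month calendar month as `"YYYY-MM"`.
#' @param term_threshold_weeks passed to [robson_classify()].
#' @return An object of class `"robson_report"`: list with `month`, `table`
#'   (a [robson_table()] or `NULL`), `trend` (data frame month / n_women /
#'   overall_cs_rate_pct / group1_cs_rate_pct), `n_invalid`. Its `print()`
#'   method renders plain text; `as.data.frame()` returns the table for CSV
#'   export.
#' @export
robson_monthly_report <- function(records, month, term_threshold_weeks = 37) {
  records <- as.data.frame(records)
  if (!"date" %in% names(records)) stop("records must carry a 'date' column",
                                        call. = FALSE)
  if (!grepl("^\\d{4}-\\d{2}$", month)) stop("month must be 'YYYY-MM'",
                                             call. = FALSE)
  rec_month <- format(as.Date(records$date), "%Y-%m")
  if (!"robson_group" %in% names(records)) {
    grp <- robson_classify(records, term_threshold_weeks, strict = FALSE)
    records$robson_group <- grp
  }
  n_invalid <- sum(is.na(records$robson_group))
  valid <- records[!is.na(records$robson_group), , drop = FALSE]
  vmonth <- rec_month[!is.na(records$robson_group)]

  in_month <- valid[vmonth == month, , drop = FALSE]
  tab <- if (nrow(in_month) > 0) robson_table(in_month) else NULL

  months <- sort(unique(vmonth[vmonth <= month]))
  trend <- do.call(rbind, lapply(months, function(m) {
    sl <- valid[vmonth == m, , drop = FALSE]
    g1 <- sl[sl$robson_group == 1L, , drop = FALSE]
    data.frame(month = m, n_women = nrow(sl),
               overall_cs_rate_pct = 100 * mean(as.logical(sl$cesarean)),
               group1_cs_rate_pct = if (nrow(g1)) 100 * mean(as.logical(g1$cesarean)) else NA_real_)
  }))
  structure(list(month = month, table = tab, trend = trend,
                 n_invalid = n_invalid),
            class = "robson_report")
}

#' @export
print.robson_report <- function(x, ...) {
  cat("Robson audit report for", x$month, "\n")
  if (is.null(x$table)) {
    cat("No births recorded in this month.\n")
  } else {
    print(x$table)
  }
  if (!is.null(x$trend) && nrow(x$trend)) {
    cat("\nTrend (overall / Group 1 cesarean rate, %):\n")
    tr <- x$trend
    tr$overall_cs_rate_pct <- round_half_up(tr$overall_cs_rate_pct, 1)
    tr$group1_cs_rate_pct <- round_half_up(tr$group1_cs_rate_pct, 1)
    print(tr, row.names = FALSE)
  }
  if (x$n_invalid > 0) {
    cat(sprintf("\nNote: %d record(s) with invalid obstetric profiles excluded.\n",
                x$n_invalid))
  }
  invisible(x)
}

#' @export
as.data.frame.robson_report <- function(x, ...) {
  if (is.null(x$table)) {
    data.frame(group = integer(), n_women = integer(), n_cesarean = integer())
  } else {
    as.data.frame(x$table)
  }
}
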
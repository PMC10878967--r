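#' Half-up rounding
#'
#' Rounds halves away from zero (so `round_half_up(0.5) == 1`), matching how
#' clinical tables are typically typeset, rather than R's banker's rounding.
#' Used only at the presentation layer; statistics are computed and stored
#' at full precision.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(c(0.05, 0.15, -0.25), 1)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# internal: stop() with a consistent prefix for schema problems
schema_stop <- function(...) stop("schema error: ", ..., call. = FALSE)
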
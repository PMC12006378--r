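# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Plain decimal rounding where a tie (x.xx5) always moves away from zero,
#' unlike [base::round()]'s round-half-even. All reported percentages in the
#' package use this rule, which is what reproduces two-decimal figures such
#' as 1/167 -> 0.60.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # small epsilon guards against values like 56.45499999... produced by
  # binary floating point for what is exactly a half
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Percentage of a genome occupied by a feature class
#'
#' @param feature_len total feature length in bp.
#' @param genome_len genome length in bp (denominator).
#' @return percentage rounded half-up to 2 decimals.
#' @export
genome_fraction <- function(feature_len, genome_len) {
  stopifnot(genome_len > 0, feature_len >= 0)
  round_half_up(100 * feature_len / genome_len, 2)
}

## classed conditions so callers/tests can distinguish failure modes
stop_classed <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "mitorecomb_error")))
}
stop_coord    <- function(fmt, ...) stop_classed("coordinate_error", fmt, ...)
stop_topology <- function(fmt, ...) stop_classed("topology_error", fmt, ...)
stop_alphabet <- function(fmt, ...) stop_classed("alphabet_error", fmt, ...)
stop_format   <- function(fmt, ...) stop_classed("format_error", fmt, ...)
stop_input    <- function(fmt, ...) stop_classed("input_error", fmt, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

# substring of a circular sequence starting at `from` (any integer, wraps
# both ways) of length `len`; len may be up to the molecule length
circ_substr <- function(s, from, len) {
  L <- nchar(s)
  if (len > L) stop_topology("requested span (%d bp) exceeds molecule length (%d bp)", len, L)
  from <- ((from - 1L) %% L) + 1L
  if (from + len - 1L <= L) {
    substr(s, from, from + len - 1L)
  } else {
    paste0(substr(s, from, L), substr(s, 1L, from + len - 1L - L))
  }
}

# positions (1-based, on the circle) covered by an interval, as integer set
circ_positions <- function(start, end, L, wraps = FALSE) {
  if (wraps) c(start:L, 1:end) else start:end
}
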
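# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base `round()` rounds half to even; printed summary tables in this field
#' round half away from zero (e.g. 102/16 = 6.375 prints as 6.38). Used for
#' all per-chromosome / per-Mb ratios and percentages.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector rounded half away from zero.
#' @keywords internal
#' @noRd
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  # nudge by a relative epsilon so that values stored as 6.374999... (binary
  # representation of 6.375) still round up
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_bad_arg <- function(msg) stop(msg, call. = FALSE)

# deterministic child seed derived from a user seed and a stream label;
# kept below 2^31 so it is always a valid R integer seed
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
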
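# Shared small helpers.

#' Round half away from zero
#'
#' Percentages in reports follow the half-up convention (95.985 -> 95.99),
#' unlike base `round()`'s round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

check_counts <- function(x, what) {
  if (any(is.na(x))) rlang::abort(sprintf("missing values in %s", what))
  if (any(x < 0)) rlang::abort(sprintf("negative counts in %s", what))
  if (any(x != floor(x))) rlang::abort(sprintf("non-integer counts in %s", what))
  invisible(x)
}

seed_stream <- function(seed, k) {
  # derive k child seeds < 2^31 deterministically from one master seed
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, k))
}
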
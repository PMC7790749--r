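# Internal helpers shared across modules.

# Condition constructors: every user-facing failure carries a subclass so
# callers (and tests) can distinguish schema, validation, usage and domain
# errors without string matching.
pb_abort <- function(message, class) {
  abort(message, class = c(class, "pathboost_error"))
}

pb_schema_error     <- function(message) pb_abort(message, "pb_schema_error")
pb_validation_error <- function(message) pb_abort(message, "pb_validation_error")
pb_usage_error      <- function(message) pb_abort(message, "pb_usage_error")
pb_domain_error     <- function(message) pb_abort(message, "pb_domain_error")

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
pb_with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    pb_usage_error("`seed` must be a single non-missing integer.")
  }
  withr::with_seed(as.integer(seed), code)
}

# Deterministically derive a sub-seed from a master seed and a stream index,
# kept inside the 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 2654435.0 + 97.0 * stream + 1.0) %% 2147483647)
}

#' Round half away from zero
#'
#' Reporting-layer rounding for printed percentages: exact halves round up
#' (`round_half_up(0.15, 1)` is 0.2), unlike base R's banker's rounding.
#' Applied only when formatting results, never inside computations.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(63.25, 63.35), 1)
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Safe ratio: NA (flagged undefined) when the denominator is zero, never a
# silent 0 -- small subgroup summaries depend on this.
safe_div <- function(num, den) {
  ifelse(den == 0, NA_real_, num / den)
}

is_fraction <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x > 0 && x < 1
}
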
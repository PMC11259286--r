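#' Round half away from zero
#'
#' Presentation rounding used in concept-mapping reports: ties round up in
#' magnitude (4.045 -> 4.05), unlike [round()]'s round-half-to-even. All
#' internal arithmetic in the package is kept at full precision; this is
#' applied only when formatting summaries.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up (away from zero).
#' @export
#' @examples
#' round_half_up(c(4.045, 3.975, -2.5), 2)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # small epsilon absorbs binary representation error of decimal inputs
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# classed conditions: validation errors (bad input data / parameters) are
# distinguished from computation errors so callers and the CLI can map them
# to distinct exit codes.
cm_abort <- function(msg, class = "cm_validation_error", call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "cm_error", "error", "condition")))
}

is_count <- function(x, min = 0L) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == as.integer(x) && x >= min
}

is_prob <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x <= 1

# population standard deviation (divide by n, not n - 1)
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# derive independent sub-stream seeds from one user-facing seed so that, e.g.,
# changing the number of raters never perturbs the generated sorts
stage_seeds <- function(seed, n = 2L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}
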
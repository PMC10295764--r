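#' Derive a reproducible sub-stream seed from a master seed
#'
#' All randomness in the package flows from a single integer master seed;
#' each operation that draws random numbers derives its own seed with a fixed
#' offset so that, e.g., the gene-parameter draw and the count draw of a
#' simulation are independent streams yet fully determined by the master.
#'
#' @param seed integer master seed.
#' @param offset integer stream offset (distinct per purpose).
#' @return an integer seed strictly below 2^31.
#' @keywords internal
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) + offset * 10007) %% .Machine$integer.max)
}

#' Round half away from zero
#'
#' Percentages are reported at full precision and additionally rounded to the
#' nearest integer with ties going up (so 51.5 -> 52), matching how integer
#' percentages are conventionally printed; base `round()` rounds ties to even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @examples
#' round_half_up(c(51.76, 95.37, 51.5))
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

assert_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_("'%s' must be a single finite number", name)
  if (positive && x <= 0) stop_("'%s' must be strictly positive", name)
  if (nonneg && x < 0) stop_("'%s' must be nonnegative", name)
  invisible(x)
}

assert_count <- function(x, name) {
  assert_scalar_number(x, name, positive = TRUE)
  if (x != as.integer(x)) stop_("'%s' must be a whole number", name)
  invisible(as.integer(x))
}

assert_fraction <- function(x, name) {
  assert_scalar_number(x, name)
  if (x < 0 || x > 1) stop_("'%s' must lie in [0, 1]", name)
  invisible(x)
}
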
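#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention used by most statistical reports (and by SPSS), as opposed to
#' the IEC 60559 round-half-even rule used by [base::round()].  The
#' distinction matters for quantities that land exactly on a rounding
#' boundary, e.g. -0.2475 prints as -0.248 under this rule.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (non-negative integer).
#' @return Numeric vector of the same length as `x`.
#' @export
#' @examples
#' round_half_up(-0.2475, 3)  # -0.248
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), digits >= 0)
  scale <- 10^digits
  # the sqrt(eps) nudge keeps values that are exact decimal ties on the
  # half-up side even when their binary representation falls a few ULP short
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

# Deterministic child-seed derivation: folds any number of integer keys into
# the master seed with a multiplicative hash mod 2^31 - 1.  Doubles are exact
# up to 2^53, so (2^31 * 69069) never loses precision.
child_seed <- function(seed, ...) {
  m <- 2147483647
  h <- as.double(seed) %% m
  for (k in c(...)) {
    h <- (h * 69069 + as.double(k) + 1) %% m
  }
  as.integer(h)
}

# Shared argument checks ------------------------------------------------

assert_probability <- function(x, name, open_lower = FALSE, open_upper = FALSE) {
  lo_ok <- if (open_lower) x > 0 else x >= 0
  hi_ok <- if (open_upper) x < 1 else x <= 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !lo_ok || !hi_ok) {
    stop(sprintf(
      "`%s` must be a single probability in %s0, 1%s, got %s",
      name, if (open_lower) "(" else "[", if (open_upper) ")" else "]",
      format(x)
    ), call. = FALSE)
  }
  invisible(x)
}

assert_binary_outcomes <- function(outcomes) {
  if (!all(outcomes %in% c(0, 1))) {
    stop("`outcomes` must be coded 0/1", call. = FALSE)
  }
  if (length(unique(outcomes)) < 2L) {
    stop("need at least one event and one non-event", call. = FALSE)
  }
  invisible(outcomes)
}
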
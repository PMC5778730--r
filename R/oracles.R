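#' Closed-form expected changes under the noise-factor model
#'
#' When a binary "risk factor" with carrier prevalence `p` is drawn
#' independently of both the baseline predicted risk and the outcome, and a
#' carrier's prediction is multiplied by `rr`, the expected values of
#' several performance changes follow in closed form (first-order, replacing
#' the realized carrier fraction by its expectation `p`; at cohort sizes in
#' the tens of thousands the neglected terms are far below three-decimal
#' rounding):
#'
#' * The mean prediction inflates by the factor `1 + p (rr - 1)`, so the
#'   calibration ratio (observed over expected) changes by
#'   `C0 / (1 + p (rr - 1)) - C0` from its baseline `C0`.
#' * The discrimination slope in each outcome stratum inflates the same way,
#'   so `IDI = p (rr - 1) (m_e - m_ne)`, where `m_e` and `m_ne` are the mean
#'   baseline risks of events and non-events.
#' * At prevalence 1 every prediction is multiplied by the same positive
#'   constant, ranks are unchanged, and the AUROC change is exactly zero
#'   (provided predictions are not capped at 1).
#'
#' No closed form is attempted for the NRI or for the AUROC change at
#' `p < 1`; those depend on the full shape of the baseline risk
#' distribution and are checked by simulation instead.
#'
#' @param c0 Baseline calibration ratio (positive).
#' @param rr Relative-risk multiplier applied to carriers, `rr >= 1`.
#' @param p Carrier prevalence in (0, 1\].
#' @param m_e,m_ne Mean baseline predicted risk among events / non-events.
#' @return A single real number.
#' @name analytic_oracles
#' @examples
#' expected_delta_calibration(0.990, 2, 1/3)  # -0.2475
#' expected_idi(0.163, 0.105, 2, 1/3)         # 0.01933
NULL

#' @rdname analytic_oracles
#' @export
expected_delta_calibration <- function(c0, rr, p) {
  stopifnot(is.numeric(c0), c0 > 0, is.numeric(rr), rr >= 1)
  assert_probability(p, "p", open_lower = TRUE)
  c0 / (1 + p * (rr - 1)) - c0
}

#' @rdname analytic_oracles
#' @export
expected_idi <- function(m_e, m_ne, rr, p) {
  assert_probability(m_e, "m_e", open_lower = TRUE, open_upper = TRUE)
  assert_probability(m_ne, "m_ne", open_lower = TRUE, open_upper = TRUE)
  stopifnot(is.numeric(rr), rr >= 1)
  assert_probability(p, "p", open_lower = TRUE)
  p * (rr - 1) * (m_e - m_ne)
}

#' @rdname analytic_oracles
#' @export
expected_delta_auroc_full_prevalence <- function() {
  0
}
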
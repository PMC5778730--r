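#' Draw a Bernoulli risk-factor assignment
#'
#' Draws independent carrier indicators, independent of both the baseline
#' predictions and the outcomes: the factor is pure noise whose only effect
#' is the multiplicative update applied to carriers' predictions.
#' Prevalence 0 and 1 are deterministic (no carriers / all carriers).
#'
#' @param n Number of subjects.
#' @param prevalence Carrier probability in \[0, 1\].
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used (as [run_condition()] does after seeding each replicate).
#' @return Integer 0/1 vector of length `n`.
#' @export
draw_risk_factor <- function(n, prevalence, seed = NULL) {
  assert_probability(prevalence, "prevalence")
  if (!is.null(seed)) set.seed(seed)
  if (prevalence == 0) return(integer(n))
  if (prevalence == 1) return(rep(1L, n))
  stats::rbinom(n, 1L, prevalence)
}

#' Apply a multiplicative risk factor to baseline predictions
#'
#' Carriers' predictions are multiplied by `rr`; non-carriers are left
#' unchanged.  By default products above 1 are *not* clamped: the updated
#' "probabilities" may exceed 1, exactly as a naive multiplicative update of
#' a published risk score would produce.  [run_condition()] counts how often
#' this occurs.  Set `cap = TRUE` to clamp at 1 (note that capping breaks
#' the exact rank invariance at prevalence 1).
#'
#' @param risks Baseline predicted risks in \[0, 1\].
#' @param carriers 0/1 carrier indicators, same length.
#' @param rr Relative-risk multiplier, `rr >= 1`.
#' @param cap Clamp updated predictions at 1? Default `FALSE`.
#' @return Numeric vector of updated predictions.
#' @export
#' @examples
#' apply_risk_factor(c(0.1, 0.3), c(1L, 0L), rr = 2)  # 0.2, 0.3
apply_risk_factor <- function(risks, carriers, rr, cap = FALSE) {
  stopifnot(length(risks) == length(carriers), rr >= 1,
            all(carriers %in% c(0, 1)))
  new <- risks * (1 + (rr - 1) * carriers)
  if (cap) new <- pmin(new, 1) else new
}

#' Simulate one (RR, prevalence, threshold) condition
#'
#' For each of `replicates` Monte-Carlo replicates: draw a fresh carrier
#' assignment, apply the multiplicative update, and compute the four change
#' statistics relative to the original model — NRI and IDI (which are
#' changes by definition), the AUROC difference, and the calibration-ratio
#' difference.  Replicate r is seeded deterministically from `(seed, r)`,
#' so any single replicate can be reproduced in isolation.
#'
#' @param cohort Cohort `data.frame` (columns `risk`, `outcome`).
#' @param rr Relative-risk multiplier, `rr >= 1`.
#' @param prevalence Carrier prevalence in (0, 1\].
#' @param threshold Intervention threshold in (0, 1); the single cutpoint
#'   defining the below/above-threshold risk categories for the NRI.
#' @param replicates Number of Monte-Carlo replicates (1 reproduces the
#'   single-realization style of a published table).
#' @param seed Integer master seed for this condition.
#' @param cap Clamp updated predictions at 1? Default `FALSE`.
#' @param nri_method Passed to [nri()].
#' @return A one-row `data.frame`: the condition, across-replicate means of
#'   `nri`, `idi`, `delta_auroc`, `delta_calibration`, their Monte-Carlo
#'   standard errors (`*_se`, SD over replicates divided by sqrt(R); `NA`
#'   for a single replicate), and `n_risks_gt1`, the mean number of updated
#'   predictions exceeding 1 per replicate.
#' @export
run_condition <- function(cohort, rr, prevalence, threshold,
                          replicates = 200L, seed = 1L, cap = FALSE,
                          nri_method = "stratified") {
  cohort <- validate_cohort(cohort)
  stopifnot(rr >= 1, replicates >= 1)
  assert_probability(prevalence, "prevalence", open_lower = TRUE)
  assert_probability(threshold, "threshold", open_lower = TRUE,
                     open_upper = TRUE)
  risks <- cohort$risk
  outcomes <- cohort$outcome
  n <- length(risks)
  base_auc <- auroc(risks, outcomes)
  base_cal <- calibration_ratio(outcomes, risks)

  draws <- matrix(NA_real_, nrow = replicates, ncol = 5)
  colnames(draws) <- c("nri", "idi", "delta_auroc", "delta_calibration",
                       "n_risks_gt1")
  for (r in seq_len(replicates)) {
    set.seed(child_seed(seed, r))
    carriers <- draw_risk_factor(n, prevalence)
    new <- apply_risk_factor(risks, carriers, rr, cap = cap)
    draws[r, ] <- c(
      nri(risks, new, outcomes, threshold, method = nri_method)$value,
      idi(risks, new, outcomes),
      auroc(new, outcomes) - base_auc,
      calibration_ratio(outcomes, new) - base_cal,
      sum(new > 1)
    )
  }
  est <- colMeans(draws)
  se <- if (replicates > 1) {
    apply(draws[, 1:4, drop = FALSE], 2, stats::sd) / sqrt(replicates)
  } else {
    rep(NA_real_, 4)
  }
  data.frame(
    rr = rr, prevalence = prevalence, threshold = threshold,
    replicates = as.integer(replicates),
    nri = est[["nri"]], idi = est[["idi"]],
    delta_auroc = est[["delta_auroc"]],
    delta_calibration = est[["delta_calibration"]],
    nri_se = se[[1]], idi_se = se[[2]], delta_auroc_se = se[[3]],
    delta_calibration_se = se[[4]],
    n_risks_gt1 = est[["n_risks_gt1"]]
  )
}

#' Sweep the three simulation panels
#'
#' Runs the study's panel layout: panel `"rr"` varies the relative risk with
#' prevalence and threshold held at `defaults`; panel `"prevalence"` varies
#' the prevalence with RR and threshold fixed; panel `"threshold"` varies
#' the intervention threshold with RR and prevalence fixed.  Conditions get
#' deterministic child seeds derived from `(seed, panel, condition)` —
#' except in the threshold panel, where all rows share one seed: the carrier
#' draws are then identical across thresholds, so the threshold-free
#' statistics (IDI, delta AUROC, delta calibration) are constant down the
#' panel and only the NRI varies, as in a single-realization study report.
#'
#' @param cohort Cohort `data.frame`.
#' @param rr_grid,prevalence_grid,threshold_grid Non-empty numeric grids.
#' @param defaults Named list giving the held-constant `rr`, `prevalence`
#'   and `threshold`.
#' @param replicates,seed,cap,nri_method As in [run_condition()].
#' @return A `data.frame` with one row per condition and a leading `panel`
#'   column (`"rr"`, `"prevalence"`, `"threshold"`).
#' @export
run_grid <- function(cohort,
                     rr_grid,
                     prevalence_grid,
                     threshold_grid,
                     defaults = list(rr = 2.0, prevalence = 1 / 3,
                                     threshold = 0.20),
                     replicates = 200L,
                     seed = 1L,
                     cap = FALSE,
                     nri_method = "stratified") {
  stopifnot(length(rr_grid) >= 1, length(prevalence_grid) >= 1,
            length(threshold_grid) >= 1,
            all(c("rr", "prevalence", "threshold") %in% names(defaults)))
  cohort <- validate_cohort(cohort)

  one_panel <- function(panel_id, panel_name, conditions) {
    rows <- lapply(seq_len(nrow(conditions)), function(i) {
      cond_seed <- if (panel_name == "threshold") {
        child_seed(seed, panel_id, 1L) # shared draws across thresholds
      } else {
        child_seed(seed, panel_id, i)
      }
      run_condition(cohort,
                    rr = conditions$rr[i],
                    prevalence = conditions$prevalence[i],
                    threshold = conditions$threshold[i],
                    replicates = replicates, seed = cond_seed, cap = cap,
                    nri_method = nri_method)
    })
    cbind(panel = panel_name, do.call(rbind, rows))
  }

  res <- rbind(
    one_panel(1L, "rr", data.frame(
      rr = rr_grid, prevalence = defaults$prevalence,
      threshold = defaults$threshold
    )),
    one_panel(2L, "prevalence", data.frame(
      rr = defaults$rr, prevalence = prevalence_grid,
      threshold = defaults$threshold
    )),
    one_panel(3L, "threshold", data.frame(
      rr = defaults$rr, prevalence = defaults$prevalence,
      threshold = threshold_grid
    ))
  )
  rownames(res) <- NULL
  res
}

#' Grids used by the published simulation study
#'
#' Relative risk 1.25 to 3.50 in steps of 0.25; prevalence 10% to 100% in
#' steps of 10%; intervention threshold 5% to 50% in steps of 5%.  The
#' held-constant values are RR = 2.0, prevalence = 1/3 and threshold = 20%.
#'
#' @return A list with elements `rr`, `prevalence`, `threshold` and
#'   `defaults`.
#' @export
paper_grids <- function() {
  list(
    rr = seq(1.25, 3.50, by = 0.25),
    prevalence = seq(0.10, 1.00, by = 0.10),
    threshold = seq(0.05, 0.50, by = 0.05),
    defaults = list(rr = 2.0, prevalence = 1 / 3, threshold = 0.20)
  )
}

#' Reproduce the full three-panel result table
#'
#' Convenience wrapper: generates the study-default synthetic cohort (see
#' [study_cohort_spec()]) and runs [run_grid()] over the published grids,
#' yielding the 30-condition result table.
#'
#' @param seed Master seed for cohort generation and all replicates.
#' @param replicates Monte-Carlo replicates per condition; 1 gives
#'   single-realization, publication-style output.
#' @param cohort Optional pre-built cohort; by default one is generated from
#'   `study_cohort_spec(seed = child seed)`.
#' @param cap,nri_method As in [run_condition()].
#' @return The 30-row `data.frame` from [run_grid()], with the cohort
#'   attached as attribute `"cohort"`.
#' @export
run_table2 <- function(seed = 1L, replicates = 200L, cohort = NULL,
                       cap = FALSE, nri_method = "stratified") {
  if (is.null(cohort)) {
    cohort <- generate_cohort(study_cohort_spec(seed = child_seed(seed, 0L)))
  }
  g <- paper_grids()
  res <- run_grid(cohort, g$rr, g$prevalence, g$threshold,
                  defaults = g$defaults, replicates = replicates,
                  seed = seed, cap = cap, nri_method = nri_method)
  attr(res, "cohort") <- cohort
  res
}
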
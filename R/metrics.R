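#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' Probability that a randomly chosen event carries a higher predicted risk
#' than a randomly chosen non-event, with ties credited 1/2 (the
#' Mann-Whitney U convention).  Computed from midranks in O(n log n) rather
#' than by enumerating all event/non-event pairs, but numerically identical
#' to the pairwise definition.
#'
#' @param risks Numeric vector of predicted risks (any monotone score works;
#'   the statistic is rank-based).
#' @param outcomes Binary 0/1 vector of the same length.
#' @return AUROC in \[0, 1\].
#' @export
#' @examples
#' auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))  # 1: perfect separation
auroc <- function(risks, outcomes) {
  stopifnot(length(risks) == length(outcomes))
  assert_binary_outcomes(outcomes)
  r <- rank(risks) # midranks: ties share the average rank, hence 1/2 credit
  n_e <- sum(outcomes == 1)
  n_ne <- length(outcomes) - n_e
  (sum(r[outcomes == 1]) - n_e * (n_e + 1) / 2) / (n_e * n_ne)
}

#' Calibration ratio (observed over expected)
#'
#' Ratio of the observed event fraction to the mean predicted risk; 1.0
#' means the model is calibrated on average, values below 1 mean the model
#' over-predicts.  With fully observed binary outcomes the observed
#' incidence is the crude event fraction.
#'
#' @param outcomes Binary 0/1 vector.
#' @param risks Predicted risks with positive mean.
#' @return Positive ratio.
#' @export
calibration_ratio <- function(outcomes, risks) {
  stopifnot(length(risks) == length(outcomes))
  if (!all(outcomes %in% c(0, 1))) stop("`outcomes` must be coded 0/1",
                                        call. = FALSE)
  mr <- mean(risks)
  if (mr <= 0) stop("mean predicted risk must be positive", call. = FALSE)
  mean(outcomes) / mr
}

#' Assign risks to ordinal categories
#'
#' Categories are the half-open intervals defined by strictly increasing
#' cutpoints in (0, 1): category k is \[cut_{k-1}, cut_k) with cut_0 = 0 and
#' an unbounded top category, so a risk exactly at a cutpoint belongs to the
#' upper category.  A single cutpoint (the intervention threshold) gives the
#' two-category below/above-threshold scheme.
#'
#' @param risks Numeric vector of risks.
#' @param cutpoints Strictly increasing probabilities in (0, 1).
#' @return Integer category per subject, 1 (lowest) to
#'   `length(cutpoints) + 1`.
#' @export
#' @examples
#' categorize(c(0.05, 0.20, 0.35), 0.20)  # 1, 2, 2
categorize <- function(risks, cutpoints) {
  validate_cutpoints(cutpoints)
  findInterval(risks, cutpoints) + 1L
}

validate_cutpoints <- function(cutpoints) {
  if (length(cutpoints) == 0L || any(cutpoints <= 0) || any(cutpoints >= 1) ||
      is.unsorted(cutpoints, strictly = TRUE)) {
    stop("`cutpoints` must be strictly increasing probabilities in (0, 1)",
         call. = FALSE)
  }
  invisible(cutpoints)
}

#' Reclassification table
#'
#' Cross-tabulates old versus new risk categories separately for events and
#' non-events.  Marginals reproduce the stratum sizes by construction.
#'
#' @inheritParams nri
#' @return A list of class `reclass_table` with integer matrices `events`
#'   and `nonevents` (rows: old category, columns: new category).
#' @export
reclassification_table <- function(old_risks, new_risks, outcomes, cutpoints) {
  stopifnot(length(old_risks) == length(new_risks),
            length(old_risks) == length(outcomes))
  k <- length(cutpoints) + 1L
  oldc <- factor(categorize(old_risks, cutpoints), levels = seq_len(k))
  newc <- factor(categorize(new_risks, cutpoints), levels = seq_len(k))
  tab <- function(sel) {
    m <- table(old = oldc[sel], new = newc[sel])
    matrix(as.integer(m), nrow = k, dimnames = dimnames(m))
  }
  structure(
    list(events = tab(outcomes == 1), nonevents = tab(outcomes == 0)),
    class = "reclass_table"
  )
}

#' @export
print.reclass_table <- function(x, ...) {
  cat("Reclassification table (rows: old category, cols: new category)\n")
  cat("Events:\n")
  print(x$events)
  cat("Non-events:\n")
  print(x$nonevents)
  invisible(x)
}

#' Net reclassification improvement
#'
#' Scores each subject +1 for movement into a higher risk category under the
#' new model and -1 for downward movement if they experienced an event, with
#' the opposite scoring for non-events.  The default (`stratified`)
#' estimator is the standard two-part NRI,
#' \deqn{NRI = [P(up|event) - P(down|event)] + [P(down|nonevent) - P(up|nonevent)],}
#' with each probability estimated within its outcome stratum; it ranges
#' over \[-2, 2\].  The `unstratified` variant divides the summed scores by
#' the total cohort size instead (range \[-1, 1\]); it is provided because
#' both readings of the informal "sum of scores over cohort members"
#' description circulate, but the stratified form is the one defined by the
#' reclassification literature and is the default throughout this package.
#'
#' @param old_risks,new_risks Predicted risks under the original and updated
#'   model.
#' @param outcomes Binary 0/1 vector; both classes must be present.
#' @param cutpoints Risk-category cutpoints, see [categorize()].
#' @param method `"stratified"` (default) or `"unstratified"`.
#' @return A list with `value`, the four movement `components`
#'   (`p_up_event`, `p_down_event`, `p_up_nonevent`, `p_down_nonevent`) and
#'   the `method` used.
#' @export
nri <- function(old_risks, new_risks, outcomes, cutpoints,
                method = c("stratified", "unstratified")) {
  method <- match.arg(method)
  stopifnot(length(old_risks) == length(new_risks),
            length(old_risks) == length(outcomes))
  assert_binary_outcomes(outcomes)
  oldc <- categorize(old_risks, cutpoints)
  newc <- categorize(new_risks, cutpoints)
  up <- newc > oldc
  down <- newc < oldc
  ev <- outcomes == 1
  n_e <- sum(ev)
  n_ne <- sum(!ev)
  comp <- c(
    p_up_event = sum(up[ev]) / n_e,
    p_down_event = sum(down[ev]) / n_e,
    p_up_nonevent = sum(up[!ev]) / n_ne,
    p_down_nonevent = sum(down[!ev]) / n_ne
  )
  value <- if (method == "stratified") {
    (comp[["p_up_event"]] - comp[["p_down_event"]]) +
      (comp[["p_down_nonevent"]] - comp[["p_up_nonevent"]])
  } else {
    score <- ifelse(ev, 1L, -1L) * (as.integer(up) - as.integer(down))
    sum(score) / length(outcomes)
  }
  list(value = value, components = comp, method = method)
}

#' Integrated discrimination improvement
#'
#' Change in the discrimination slope: the difference between the mean
#' predicted risk of events and of non-events, under the new model minus
#' under the original model.  Positive values mean the new model increases
#' predictions for events and/or decreases them for non-events.
#'
#' @inheritParams nri
#' @return A single real number.
#' @export
idi <- function(old_risks, new_risks, outcomes) {
  stopifnot(length(old_risks) == length(new_risks),
            length(old_risks) == length(outcomes))
  assert_binary_outcomes(outcomes)
  ev <- outcomes == 1
  (mean(new_risks[ev]) - mean(new_risks[!ev])) -
    (mean(old_risks[ev]) - mean(old_risks[!ev]))
}
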
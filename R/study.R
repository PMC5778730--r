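#' Configuration for a full study reproduction
#'
#' Bundles the cohort specification, the three parameter grids, the
#' held-constant defaults, the replicate count and the master seed.  A
#' config can be written to / read from YAML, with the cohort spec under the
#' `cohort:` key and grids under `grids:`.
#'
#' @param cohort A [cohort_spec()]; default [study_cohort_spec()].
#' @param grids Named list with numeric `rr`, `prevalence`, `threshold`;
#'   default [paper_grids()] (without its `defaults` element).
#' @param defaults Held-constant `rr`, `prevalence`, `threshold`.
#' @param replicates Monte-Carlo replicates per condition.
#' @param seed Master seed.
#' @param cap,nri_method Passed through to [run_condition()].
#' @return A list of class `study_config`.
#' @export
study_config <- function(cohort = study_cohort_spec(),
                         grids = paper_grids()[c("rr", "prevalence", "threshold")],
                         defaults = paper_grids()$defaults,
                         replicates = 200L,
                         seed = 1L,
                         cap = FALSE,
                         nri_method = "stratified") {
  stopifnot(inherits(cohort, "cohort_spec"),
            all(c("rr", "prevalence", "threshold") %in% names(grids)),
            all(lengths(grids[c("rr", "prevalence", "threshold")]) >= 1),
            all(c("rr", "prevalence", "threshold") %in% names(defaults)),
            replicates >= 1)
  structure(
    list(cohort = cohort, grids = grids, defaults = defaults,
         replicates = as.integer(replicates), seed = as.integer(seed),
         cap = cap, nri_method = nri_method),
    class = "study_config"
  )
}

#' @rdname study_config
#' @param path YAML file path.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$cohort)) stop("config must contain a `cohort:` block",
                              call. = FALSE)
  spec <- do.call(cohort_spec, y$cohort)
  args <- y[setdiff(names(y), "cohort")]
  do.call(study_config, c(list(cohort = spec), args))
}

#' @rdname study_config
#' @param config A `study_config`.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  y <- unclass(config)
  y$cohort <- Filter(Negate(is.null), unclass(y$cohort))
  yaml::write_yaml(y, path, precision = 17)
  invisible(path)
}

#' Reproduce the simulation study end to end
#'
#' Generates the synthetic cohort, sweeps the three panels, and writes four
#' artefacts to `out_dir`:
#' \describe{
#'   \item{`cohort.csv`}{the generated cohort (see [write_cohort()]).}
#'   \item{`results.csv`}{one row per condition (30 rows under the default
#'     grids), in the three-panel table layout.}
#'   \item{`oracle_comparison.csv`}{per condition, the closed-form expected
#'     IDI and calibration change computed from the cohort's own sample
#'     moments ([expected_idi()], [expected_delta_calibration()]), the
#'     simulated means, and their standardized differences
#'     `|simulated - oracle| / MC SE`.}
#'   \item{`run_log.yaml`}{the full configuration (sufficient to reproduce
#'     the run), package and R versions, the baseline AUROC and calibration
#'     of the generated cohort, and the total count of updated predictions
#'     exceeding 1.}
#' }
#' Identical config + seed give bit-identical outputs.  If any stage fails,
#' files already written are removed before the error propagates.
#'
#' @param config A [study_config()].
#' @param out_dir Output directory (created if needed).
#' @param paper_style If `TRUE`, also round the statistic columns of
#'   `results.csv` to three decimals (half away from zero), the precision of
#'   a published table; full-precision columns are kept alongside.
#' @return Invisibly, a list with the `cohort`, the `results` table, the
#'   `oracle_comparison` table and the output `paths`.
#' @export
reproduce_study <- function(config = study_config(), out_dir = "study_output",
                            paper_style = FALSE) {
  stopifnot(inherits(config, "study_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c(cohort = "cohort.csv", results = "results.csv",
                                oracle = "oracle_comparison.csv",
                                log = "run_log.yaml"))
  names(paths) <- c("cohort", "results", "oracle", "log")
  written <- character(0)
  on_fail <- function(stage, e) {
    unlink(written)
    stop(sprintf("study stage `%s` failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  }

  spec <- config$cohort
  if (is.null(spec$seed)) {
    spec$seed <- child_seed(config$seed, 0L)
  }
  cohort <- tryCatch(generate_cohort(spec),
                     error = function(e) on_fail("generate_cohort", e))
  tryCatch(write_cohort(cohort, paths[["cohort"]]),
           error = function(e) on_fail("write_cohort", e))
  written <- c(written, paths[["cohort"]])

  results <- tryCatch(
    run_grid(cohort,
             rr_grid = config$grids$rr,
             prevalence_grid = config$grids$prevalence,
             threshold_grid = config$grids$threshold,
             defaults = config$defaults,
             replicates = config$replicates,
             seed = config$seed,
             cap = config$cap,
             nri_method = config$nri_method),
    error = function(e) on_fail("run_grid", e)
  )
  out_results <- results
  if (paper_style) {
    for (col in c("nri", "idi", "delta_auroc", "delta_calibration")) {
      out_results[[paste0(col, "_3dp")]] <- round_half_up(results[[col]], 3)
    }
  }
  tryCatch(utils::write.csv(out_results, paths[["results"]], row.names = FALSE),
           error = function(e) on_fail("write_results", e))
  written <- c(written, paths[["results"]])

  oracle_cmp <- tryCatch(
    oracle_comparison(cohort, results),
    error = function(e) on_fail("oracle_comparison", e)
  )
  tryCatch(utils::write.csv(oracle_cmp, paths[["oracle"]], row.names = FALSE),
           error = function(e) on_fail("write_oracle_comparison", e))
  written <- c(written, paths[["oracle"]])

  log <- list(
    config = local({
      y <- unclass(config)
      y$cohort <- Filter(Negate(is.null), unclass(spec))
      y
    }),
    package_version = as.character(utils::packageVersion("riskreclass")),
    r_version = R.version.string,
    baseline_auroc = auroc(cohort$risk, cohort$outcome),
    baseline_calibration = calibration_ratio(cohort$outcome, cohort$risk),
    total_risks_gt1 = sum(results$n_risks_gt1 * results$replicates)
  )
  tryCatch(yaml::write_yaml(log, paths[["log"]], precision = 17),
           error = function(e) on_fail("write_log", e))

  invisible(list(cohort = cohort, results = results,
                 oracle_comparison = oracle_cmp, paths = paths))
}

# Closed-form expectations evaluated at the cohort's own sample moments,
# side by side with the simulated means.
oracle_comparison <- function(cohort, results) {
  ev <- cohort$outcome == 1
  m_e <- mean(cohort$risk[ev])
  m_ne <- mean(cohort$risk[!ev])
  c_obs <- calibration_ratio(cohort$outcome, cohort$risk)
  oracle_idi <- mapply(expected_idi, rr = results$rr, p = results$prevalence,
                       MoreArgs = list(m_e = m_e, m_ne = m_ne))
  oracle_dcal <- mapply(expected_delta_calibration, rr = results$rr,
                        p = results$prevalence, MoreArgs = list(c0 = c_obs))
  # at prevalence 1 the carrier draw is deterministic: MC SE is 0 and the
  # simulated value matches the oracle exactly, so the z-score is 0
  zscore <- function(diff, se) {
    ifelse(se > 0, abs(diff) / se, ifelse(abs(diff) <= 1e-10, 0, Inf))
  }
  data.frame(
    panel = results$panel, rr = results$rr, prevalence = results$prevalence,
    threshold = results$threshold,
    idi = results$idi, oracle_idi = oracle_idi,
    idi_z = zscore(results$idi - oracle_idi, results$idi_se),
    delta_calibration = results$delta_calibration,
    oracle_delta_calibration = oracle_dcal,
    delta_calibration_z = zscore(results$delta_calibration - oracle_dcal,
                                 results$delta_calibration_se)
  )
}
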
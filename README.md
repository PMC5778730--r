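# riskreclass

Tools for asking a deceptively simple question in clinical risk prediction:
when a new risk factor is bolted onto an existing prediction model, do the
usual performance measures agree on whether the model got better?

The package grew out of fracture-risk prediction. An established tool (such
as FRAX®) assigns each patient a 10-year probability of major osteoporotic
fracture (MOF); investigators continually propose new markers to add to it.
`riskreclass` simulates the canonical worst case — a *noise* factor: a
binary marker X ~ Bernoulli(p), independent of both the outcome and the
existing predictions, whose assumed relative risk RR simply multiplies a
carrier's predicted probability:

    pi_new_i = pi_i * RR^{X_i}

For each condition on a grid of RR, carrier prevalence p, and intervention
threshold t, it measures the change in four performance statistics between
the original and updated model:

* **AUROC** (Mann–Whitney estimator, ties credited 1/2) — discrimination;
* **calibration ratio** = observed event fraction / mean predicted risk;
* **NRI**, the net reclassification improvement
  `[P(up|event) − P(down|event)] + [P(down|non-event) − P(up|non-event)]`
  with categories defined by the intervention threshold;
* **IDI**, the change in discrimination slope
  `[mean(new|events) − mean(new|non-events)] − [mean(old|events) − mean(old|non-events)]`.

Because the factor carries no information, discrimination and calibration
can only degrade — yet the reclassification statistics NRI and IDI are
positive over most of the grid. The package reproduces that dissociation
end to end: a synthetic cohort generator emulating a 31,999-woman BMD
registry cohort (event-group risk 16.3% ± 9.6%, non-event 10.5% ± 6.8%,
baseline calibration 0.990), the four metrics, the Monte-Carlo sweep over
the published grids, and closed-form expected values
(`IDI = p (RR−1) (m_e − m_ne)`,
`ΔCal = C0/(1 + p(RR−1)) − C0`, and ΔAUROC = 0 exactly at p = 1) that serve
as independent oracles for the simulation.

Intended users: biostatisticians and methodologists studying added
predictive value, and anyone who wants a reproducible, fully testable
reference implementation of NRI/IDI/ΔAUROC/Δcalibration under marker
injection.

## Worked example

```r
library(riskreclass)

spec   <- study_cohort_spec(seed = 2024)   # registry-like synthetic cohort
cohort <- generate_cohort(spec)

auroc(cohort$risk, cohort$outcome)                 # 0.677
calibration_ratio(cohort$outcome, cohort$risk)     # 0.990

res <- run_condition(cohort, rr = 2, prevalence = 1/3, threshold = 0.20,
                     replicates = 200, seed = 2024)
res[, c("nri", "idi", "delta_auroc", "delta_calibration")]
#>      nri    idi delta_auroc delta_calibration
#>   0.0389 0.0156     -0.0179           -0.2475

expected_delta_calibration(0.990, 2, 1/3)          # -0.2475
expected_idi(0.163, 0.105, 2, 1/3)                 # 0.0193
```

Reading: the injected factor (RR = 2, carried by a third of the cohort)
*improves* both reclassification statistics (NRI +0.039, IDI +0.016) while
discrimination drops (ΔAUROC −0.018) and the model drifts into
over-prediction (calibration ratio falls by 0.2475, exactly the closed-form
`0.990/(4/3) − 0.990`). The IDI oracle evaluated at the published group
means (0.163/0.105) gives 0.0193; the simulated cohort's own group means
are slightly closer together, hence 0.0156.

`run_table2(seed, replicates)` runs all three published panels (RR varying,
prevalence varying, threshold varying; 30 conditions), and
`reproduce_study()` additionally writes the cohort, the results table, a
per-cell comparison against the closed-form oracles, and a run log
sufficient to reproduce the run bit for bit.

## Vignette

`vignettes/noise-risk-factor-simulation.Rmd` documents the model and its
assumptions, the generator's design (beta group distributions, the
outcome-first/risk-first modes, why the study default pins calibration
rather than the crude event rate), numerical conventions (tie handling,
category boundaries, seed derivation, rounding), and what the synthetic
cohort can and cannot say about the original registry data.
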
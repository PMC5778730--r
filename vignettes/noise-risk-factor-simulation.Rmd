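---
title: "Injecting a noise risk factor into a fracture-risk model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Injecting a noise risk factor into a fracture-risk model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskreclass)
```

## The model

Each subject $i$ in a cohort of size $n$ carries a baseline 10-year
predicted probability of major osteoporotic fracture $\pi_i \in [0,1]$ and
a fully observed binary outcome $D_i$. A hypothetical new risk factor is a
carrier indicator $X_i \sim \mathrm{Bernoulli}(p)$ drawn independently of
both $\pi_i$ and $D_i$ — a *noise* factor. The "new model" multiplies a
carrier's prediction by an assumed relative risk $RR \ge 1$:

$$\pi^{new}_i = \pi_i \, RR^{\,X_i}.$$

The independence assumption is the crux of the design. A factor that truly
carried $RR$-fold risk would improve discrimination; a factor whose
*assumed* effect merely rescales predictions cannot. Two observable
consequences pin this reading down: the integrated discrimination
improvement comes out as $p\,(RR-1)\,(m_e - m_{ne})$ (linear in prevalence,
matching the published prevalence panel cell for cell), and the AUROC
change is negative throughout — both impossible if the factor were
informative. Products $\pi_i RR$ above 1 are deliberately *not* clamped by
default: clamping would break the exact rank-invariance of the AUROC at
$p = 1$ and the closed form for the calibration change at large $RR$. The
number of predictions pushed above 1 is counted and reported per condition
(`n_risks_gt1`); a `cap = TRUE` option exists for sensitivity analyses. No
recentring of the updated predictions to preserve the cohort mean is
applied, for the same reason.

## The four change statistics

* **AUROC** uses the Mann–Whitney estimator with ties credited $1/2$
  (computed from midranks; identical to all-pairs enumeration, which the
  test suite verifies by brute force on small cohorts).
* **Calibration ratio** is the observed event fraction divided by the mean
  predicted risk. With fully observed binary outcomes the "observed
  incidence" is the crude event fraction; this is a documented divergence
  from registry practice, where the numerator is a censoring-adjusted
  10-year cumulative incidence.
* **NRI**: categories are half-open intervals $[c_{k-1}, c_k)$ with a risk
  exactly at a cutpoint assigned to the *upper* category (the boundary
  convention is ours; with $RR \ge 1$ no subject can cross downwards, so
  only the upward boundary matters). The default estimator is the
  stratified two-part NRI,
  $[\hat P(\mathrm{up}\mid e) - \hat P(\mathrm{down}\mid e)] +
   [\hat P(\mathrm{down}\mid ne) - \hat P(\mathrm{up}\mid ne)]$,
  with range $[-2, 2]$. The informal description "sum of individual
  scores divided by the number of cohort members" that circulates for this
  statistic literally defines an unstratified index with range $[-1, 1]$;
  both are implemented (`method = "unstratified"`), the stratified form is
  the default because it is the one defined in the reclassification
  literature, and on a real cohort the two generally differ.
* **IDI** is the change in discrimination slope; with a multiplicative
  noise factor it obeys the exact per-realization identity
  $IDI = (RR-1)\left[\overline{X\pi}^{(e)} - \overline{X\pi}^{(ne)}\right]$,
  which the tests check subject by subject.

## Closed-form oracles

Replacing the realized carrier fraction by its expectation $p$ (error
$O(n^{-1/2})$, far below three-decimal rounding at $n \approx 32{,}000$):

$$E[\Delta \mathrm{Cal}] = \frac{C_0}{1 + p(RR-1)} - C_0, \qquad
  E[IDI] = p\,(RR-1)\,(m_e - m_{ne}), \qquad
  \Delta \mathrm{AUROC}\big|_{p=1} = 0 \text{ (exact)},$$

where $C_0$ is the baseline calibration ratio and $m_e, m_{ne}$ the group
mean risks. No closed form is attempted for the NRI or for
$\Delta\mathrm{AUROC}$ at $p < 1$; both depend on the whole shape of the
baseline risk distribution and are checked by simulation against
brute-force scoring instead. The "prevalence 33%" of the held-constant
condition is taken as exactly $1/3$: at $RR = 3.5$ the closed-form
calibration change is $-0.450$ under $p = 1/3$ but $-0.448$ under
$p = 0.33$, and only the former matches the published cell.

## The synthetic cohort generator

No individual-level data from the source registry are available, so every
downstream stage runs on synthetic cohorts that reproduce its summary
structure: $n = 31{,}999$ women, event-group predicted risk
$16.3\% \pm 9.6\%$, non-event group $10.5\% \pm 6.8\%$, event-group weight
$3182/31999 \approx 9.9\%$, baseline AUROC near 0.706, baseline calibration
0.990.

Within each outcome group the predicted risk follows a **beta
distribution** moment-matched to the group mean and SD — the natural
two-parameter family on $(0,1)$; the published moments are feasible
($s^2 < m(1-m)$ in both groups) and infeasible requests fail with the
offending group named. The family choice is a genuine degree of freedom:
the registry's actual risk distribution is not beta, and the rank-based
AUROC depends on distribution shape beyond the first two moments. Under the
beta family the baseline AUROC comes out at $0.689$ (SD $0.005$ across
seeds), close to but systematically below the registry's $0.706$; the test
suite asserts the value to a tolerance of $0.03$ chosen from a 100-seed
simulation of exactly this family effect.

Two generation modes resolve an inconsistency that any fully observed
binary emulation of the registry must face: the crude event fraction
(9.9%), the overall mean risk ($\approx 11.1\%$), and the calibration ratio
(0.990) cannot all hold at once, because the registry's 0.990 uses a
censoring-adjusted incidence numerator ($0.099/0.111 \approx 0.90$).

* `outcome_first` (the constructor default): outcomes first, group risks
  second. Matches the published group moments and event rate directly;
  calibration is emergent ($\approx 0.90$).
* `risk_first`: risks from the outcome-weighted mixture, then
  $D_i \sim \mathrm{Bernoulli}(\min(1, C_0\pi_i))$, so the expected
  calibration ratio equals the target $C_0$. With `exact_counts = TRUE`
  the event count is fixed at $\mathrm{round}(C_0 \sum \pi_i)$ and events
  are sampled with probability proportional to $\pi$, pinning the realized
  ratio at $C_0$ to within $1/n$.

The **study default** (`study_cohort_spec()`) uses `risk_first` with exact
counts and $C_0 = 0.990$: the calibration-change results — the quantities
that are analytically forced and reproduced to printed precision — depend
on the baseline ratio, not on the crude event rate. The cost is emergent
quantities that drift slightly from the published descriptives: event
fraction $\approx 0.110$, event-group mean risk $\approx 0.155$ (the
$\pi$-weighted selection pulls the groups together), hence a simulated IDI
at the held-constant condition of $\approx 0.016$ against $0.019$ from the
published group means. Simulation-versus-oracle checks therefore always
evaluate the oracles at the *cohort's own* sample moments, and the
printed-precision IDI checks use the published moments directly.

Bernoulli event draws are the default; the exact-count option removes one
Monte-Carlo noise source and is used by the study configuration.

## Monte-Carlo design and seeds

Each condition runs $R = 200$ replicates by default (a published table of
this kind is typically a single realization; `replicates = 1` reproduces
that style, and the across-replicate SD/$\sqrt{R}$ is reported as the MC
standard error of every statistic). One master seed drives everything;
child seeds are derived deterministically per (panel, condition, replicate)
by a multiplicative hash modulo $2^{31}-1$, so any single cell or replicate
is reproducible in isolation. In the threshold panel all ten rows share the
same condition seed: RR and prevalence are fixed there, so the carrier
draws are identical across thresholds and the threshold-free statistics
(IDI, ΔAUROC, ΔCalibration) are constant down the panel — exactly the
structure of the published table.

The full reproduction (30 conditions × 200 replicates at $n = 31{,}999$,
`run_table2()`) takes roughly 1–2 minutes on one CPU; the test suite uses
the same sizes for the end-to-end checks and much smaller cohorts
elsewhere.

## Numerical conventions and edge cases

* Ties in the AUROC get $1/2$ credit; all-equal risks give exactly $0.5$.
* A risk exactly at a cutpoint belongs to the upper category.
* Prevalence 0 and 1 are deterministic carrier assignments, not Bernoulli
  draws, so the $p = 1$ rank-invariance ($\Delta\mathrm{AUROC} = 0$) holds
  *exactly*, to the last bit.
* $RR = 1$ gives identically zero deltas with zero MC error.
* Publication-style rounding (`round_half_up()`, the `paper_style` output)
  breaks ties away from zero — the convention of most statistical software
  reports — with a $\sqrt{\varepsilon}$ nudge so that exact decimal ties
  whose binary representation falls a few ULP short still round up. This
  matters: the closed-form calibration change at the held-constant
  condition is exactly $-0.2475$, which prints as $-0.248$ only under this
  rule. Because that expectation sits *on* a three-decimal rounding
  boundary, the end-to-end check asserts the two-step chain (simulated mean
  within 3 MC SE of the closed form; closed form rounds to the printed
  cell) rather than asking a Monte-Carlo mean to round deterministically.
* Degenerate inputs error early and by name: single-class outcomes for any
  discrimination statistic, all-zero risks for calibration, infeasible
  group moments, malformed cohort CSV rows (with the row number).

## What passing tests do and do not show

The synthetic world validates the *machinery* and every analytically forced
quantity: metric implementations against brute-force enumeration, the
simulation against its closed forms, the printed calibration-change rows
and IDI spot-check cells, the exact $p = 1$ invariance, and the published
qualitative structure (ΔAUROC $\le 0$ under noise injection, calibration
change decreasing in $RR$ and $p$, NRI rising then falling in $RR$ with an
interior maximum — the peak lands at $RR = 1.75$ here versus $2.0$ in the
registry). It does not reproduce registry-dependent magnitudes: published
NRI values and ΔAUROC at $p < 1$ depend on the real cohort's risk
distribution, and the synthetic beta family shifts them (e.g. baseline
AUROC 0.689 versus 0.706). Real predicted-risk distributions are also
lumpier than any smooth family — calculator outputs cluster and heap at
round values — which chiefly affects threshold-crossing quantities like the
NRI. One published oddity is knowingly ignored: the threshold panel of the
source table prints a constant ΔAUROC of $-0.291$ while the identical
condition in the RR panel gives $-0.027$; the former is almost certainly a
typesetting artifact, and nothing in this package targets it.

## Limitations

Single dichotomous factor only; no correlated or continuous markers; no
survival/censoring machinery (binary outcomes stand in for 10-year
cumulative incidence); no confidence intervals for NRI/IDI beyond the MC
standard errors of the simulation itself.
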
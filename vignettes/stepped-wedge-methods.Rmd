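---
title: "Design and analysis methods for stepped-wedge trials of intrapartum care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design and analysis methods for stepped-wedge trials of intrapartum care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweptrial)
```

`sweptrial` implements the design and analysis machinery of a
cross-sectional stepped-wedge cluster-randomized trial of labour and
childbirth care in a handful of high-volume maternity hospitals: Robson
ten-group classification with audit tables, modified-Poisson generalized
estimating equations (GEE) with small-sample-corrected inference, power
calculation under nested-exchangeable correlation, and a calibrated
synthetic-data generator so every stage can be exercised without access to
patient-level data. This vignette is the package's account of the methods,
the defaults, and the design choices that were genuinely open.

## The design

In a cross-sectional stepped wedge, every cluster (here: hospital) starts
under the control condition and crosses over to the intervention at a
randomly assigned, staggered step; all clusters finish under the
intervention. `sw_design()` encodes the geometry; the package's reference
geometry (`default_trial_design()`) has four clusters, seven 61-day
(two-month) analysis periods starting 1 July 2021, one crossover per step,
and a trial end of 15 July 2022, which truncates the seventh period to 14
days. A 14-day transition window after each crossover is excluded from
analysis — the intervention needs time to bed in, and births during that
window belong to neither condition cleanly. Exposure is always *planned*
exposure: condition is derived from the randomization schedule and the
birth date, never from a recorded condition column (intention-to-treat at
the cluster-period level).

```{r design}
d <- default_trial_design()
exposure_matrix(d, mark_transition = TRUE)
```

## Robson classification

Births are classified into the ten mutually exclusive, all-inclusive Robson
groups from parity, previous cesarean, labor onset, fetal presentation/lie,
number of fetuses, and term status. The hierarchy (multiple pregnancy
first, then lie, breech, preterm cephalic, previous cesarean, and finally
the four low-risk groups split by parity and onset) follows the WHO
implementation manual; the ten-group version is used, without the 2a/2b,
4a/4b or 5.1/5.2 subdivisions. Term means at least 37 completed weeks,
configurable via `term_threshold_weeks`. Women with a previous cesarean
who are preterm cephalic go to Group 10, breech to Group 7, transverse to
Group 9 — Group 5 holds only term cephalic singletons. The classifier is a
total function over valid profiles: the test suite checks it cell by cell
against an independently hand-encoded predicate table over the full
covariate grid, plus property tests on random profiles.

Records with invalid profiles (a previous-cesarean count exceeding parity,
an unknown onset) are rejected with an error naming the field; the monthly
audit report (`robson_monthly_report()`) instead excludes them and counts
them in a footer, since a feedback meeting should see the table even when a
register holds a few malformed rows.

## Effect estimation

The trial's estimand for binary outcomes is a population-average relative
risk. `gee_mp()` fits the "modified Poisson" model — log link and Poisson
variance applied to a binary outcome — by GEE with an exchangeable working
correlation: the linear predictor holds an intercept, the treatment
indicator, and fixed effects for calendar period (reference: first observed
period), nothing else. Fitted probabilities above 1 are possible under the
log link; they are flagged in diagnostics but not clamped, because clamping
would change the estimating equations.

Numerics worth recording:

* The exchangeable inverse uses the closed form for `((1-a)I + aJ)^(-1)`,
  so clusters of thousands of women cost linear time and no cluster-sized
  matrix is ever formed (the Mancl-DeRouen leverage inverse goes through
  the Woodbury identity the same way).
* The scale is the mean squared Pearson residual; the working correlation
  is the moment estimator — standardized residual cross-products averaged
  over all within-cluster pairs, divided by the scale.
* The two-step (coefficients, correlation) iteration can enter a slow
  near-cycle on small sparse datasets, so the correlation update is damped
  (averaged with its previous value) after the first ten iterations, and
  convergence requires both a maximum coefficient step below `tol`
  (default 1e-8) and a stable correlation (1e-6). The damping does not
  move the fixed point. Default iteration cap: 200. Non-convergence is
  returned as an explicitly flagged last iterate, never silently.

With four clusters the usual robust sandwich variance is badly biased
downward, so inference uses the Mancl-DeRouen bias-corrected sandwich —
cluster residuals inflated by the inverse of (identity minus cluster
leverage) — paired with a t reference on `N_clusters - 2` degrees of
freedom, the most conservative of the standard small-sample pairings.
`sandwich_variance()` exposes all three flavours (model-based, plain
sandwich, Mancl-DeRouen); the suite verifies each against dense-matrix hand
computation on small fixtures to 1e-8 and checks that the correction
shrinks toward the plain sandwich as clusters grow. Duration outcomes (days
from admission to childbirth, childbirth to discharge) are reported as raw
intervention-minus-control mean differences, with the interval taken from
an identity-link Gaussian GEE with the same correction — the crude
difference is the quoted effect size, the model supplies the uncertainty.

The ICC of the primary outcome is estimated on control-period data as the
fitted exchangeable correlation of the same model without the treatment
term. For a binary outcome the Poisson-variance Pearson normalization
cancels, so this recovers the outcome-scale ICC. The interval is a seeded
cluster bootstrap (2,000 resamples by default; the pipeline uses a smaller
default of 200 for routine runs), lower bound truncated at zero. Whether
the original analysis used a bootstrap or a model-based interval is not
stated in the trial report; the bootstrap was chosen as the assumption-light
option and is configurable. One behaviour worth knowing: with only four
clusters the moment estimator of the ICC is attenuated on the order of
1/K, because the fitted marginal means absorb part of the cluster effects.
The acceptance suite measures this directly — recovery of a true ICC of
0.02 holds within 0.005 on a 12-cluster wedge, while the 4-cluster estimate
averages ~30% low. A trial of this geometry reporting an ICC slightly below
its design assumption is exactly what this predicts.

## Power

`power_closed_form()` computes design power by generalized least squares
on cluster-period means. Each cluster contributes a `T x T` covariance
block with diagonal `sigma2 * (1 + (m_eff - 1) * rho) / m_eff` and
off-diagonal `sigma2 * rho * r`, where `sigma2 = p(1-p)` at the midpoint of
the two proportions, `rho` is the within-period ICC and `r` the cluster
autocorrelation (between-period correlation `rho * r`). Unequal
cluster-period sizes enter through `m_eff = m / (1 + cv^2)`.

That unequal-size adjustment was a genuinely open choice. The relative-
efficiency form above was adopted after rejecting the alternative
`m_eff = m * (1 + cv^2)`: substituting the inflated size into both the
correlation penalty and the sampling term makes computed power *increase*
with size variability, which is physically backwards. The adopted form
degrades information with CV, and on the reference geometry with the
design inputs of the emulated trial (control rate 40%, a 25% relative
reduction, ICC 0.02, CAC 0.90, 300 women per cluster-period, CV 0.60,
two-sided 5% alpha) it gives:

```{r power}
power_closed_form(0.40, 0.30, icc = 0.02, cac = 0.90,
                  mean_cluster_period_size = 300, cv_cluster_size = 0.60)
```

i.e. 93.2%, matching the 92% such a design is quoted to provide to within
the precision the competing published adjustments allow. Periods shorter
than the nominal length (the truncated seventh period) recruit
proportionally fewer women in the calculation; ignoring the truncation
would report 94.1%.

`power_by_simulation()` validates this end to end: it generates full
individual-level trials (a pure Robson Group 1 population at the requested
size, CV, ICC and CAC), analyzes each exactly as the trial would, and
reports two kinds of quantity that must not be conflated:

* the **information-based power** (`power`) — the two-sided z power implied
  by the mean and standard deviation of the treatment-effect estimates
  across replicates. This is the quantity a known-variance design formula
  predicts, and the closed form lands within a few MC half-widths of it at
  the design inputs. The agreement is genuinely borderline rather than
  comfortable: the realized GEE pays a measurable efficiency premium
  (roughly 5-10% on the SE) over the known-variance GLS bound — part
  single-alpha working correlation against a nested truth, part estimated
  correlation, part log-scale estimation — which the conservative
  `1/(1+cv^2)` derating only partly offsets. At equal cluster sizes, or at
  mid-power configurations, the two can disagree by 3-5 points in either
  direction. The closed form should be read as a design-stage
  approximation with that resolution, which is also the resolution at
  which the competing published adjustments disagree with each other.
* the **realized rejection fractions** of the tests a four-cluster trial
  could actually run. These spread dramatically at the design inputs:
  the uncorrected sandwich with a normal reference rejects far too often
  (anti-conservative, measured type I error above 30% under the null at
  small sizes), while the trial's own conservative rule — Mancl-DeRouen
  with t(2) — rejects a true 25% reduction only about a fifth of the time.
  No variance estimator concentrates with four clusters; this is the
  central caveat on small stepped wedges, and the reason the package
  reports the information-based power and the operating characteristics
  separately instead of pretending one number serves both purposes.

The null behaves as designed: effect estimates centre on zero, the
conservative tests reject at or below nominal rate, and the coverage
ordering (Mancl-DeRouen + t covers at least as often as sandwich + normal,
within [0.90, 1]) is asserted over 500 null trials in the acceptance suite.

## The synthetic-data generator

`generate_trial()` emulates the structure the analysis assumes, not any
patient's data. Defaults describe a four-hospital population of roughly
1,100 women per hospital per two-month period (size CV 0.60, log-normal):
47% nulliparous; among multiparous women 56% / 35.5% / 8.5% with 0 / 1 / 2+
previous cesareans; 1% twin pregnancies; 3.5% breech and 0.5% transverse
lie; onset 76% spontaneous, 14% induced, 10% prelabor cesarean.
Gestational age is a two-component normal mixture (term component at 39.1
weeks SD 1.1; an early-delivery component at 32.5 weeks SD 3.0 with
probability 0.10), giving mean ~38.4, SD ~2.4 and ~12% preterm — a single
normal with the population's printed mean and SD would put over 20% of
births preterm and distort the Robson mix. Group-specific baseline cesarean
probabilities are set so the control-period mix reproduces the audit-table
shape of such settings (Group 1 near 30% of women with a cesarean rate in
the mid-40s; overall cesarean near 50%); prelabor-cesarean women are
cesarean by definition. The default intervention effect is a relative risk
of 0.85 on cesarean among laboring women, with secondary-outcome baselines
and effects configurable the same way. Denominator logic mirrors the
analysis tables: augmentation and membrane rupture are defined only for
spontaneous labor, episiotomy and operative vaginal birth only for vaginal
births, cesarean and operative vaginal birth are mutually exclusive, and
babies are counted per woman (`n_babies`, `n_stillbirths`,
`n_neonatal_deaths`) so women-level and baby-level denominators can differ.
The postpartum-survey subsample flag follows the Robson-1-or-3, liveborn,
last-15-days-of-period rule.

Correlation is induced on the latent logit scale with nested normal random
effects — a cluster effect shared by all of a hospital's women and a
cluster-period effect — while the targets (ICC, CAC) are stated on the
outcome scale, where power conventions live.
`solve_variance_components()` bridges the scales deterministically: nested
bisection with 40-node Gauss-Hermite quadrature for the logit-normal
moments, re-centring the intercept so the marginal rate stays on target.
The solver's induced ICC and CAC are verified in the suite by large-sample
Monte-Carlo integration to 1e-3, and the generator's realized outcome-scale
correlations by a pairwise moment estimator on a wide (20-cluster) wedge to
0.005. Variance components are calibrated at the primary-outcome (Group 1)
baseline and shared across the correlated outcomes; other outcomes'
marginal rates are hit exactly by per-cell intercept re-centring, but their
induced ICCs vary slightly with their baselines — a deliberate
simplification.

What the generator does *not* emulate: seasonality and secular trends
beyond the step structure, within-cluster provider effects, covariate-
outcome confounding (cesarean risk depends on Robson group but covariates
are drawn independently of the random effects), record-level missingness,
and any real hospital's identifiable patterns. Passing tests therefore
demonstrate that the estimators recover what this generative model puts in,
at the trial's geometry — not that any specific published estimate is
reproduced, which would require the deposited patient-level data.

## The analysis pipeline

`run_trial_analysis()` chains the stages: schema validation, planned-
exposure assignment (with a warning when a recorded condition column
disagrees), transition exclusion (counted and reported), evaluation of
every outcome specification (crude rates by arm at full precision, half-up
rounding only at the presentation layer; relative risks with
Mancl-DeRouen + t(N-2); mean differences for durations), trial-flow counts
by cluster and condition, and the control-period ICC report. A model that
fails to converge produces a row with crude statistics and an explicit
"no estimate" marker — a real feature, since rare outcomes with extreme
between-hospital variability do defeat the log-link fit, as the emulated
trial itself reported for one outcome. Everything is deterministic given
the input data and seed; the suite asserts byte-identical JSON across
repeated runs.

## Problem sizes in the test suite

The suite is sized to validate, not to torture: oracle equivalence runs on
12-row to ~300-row fixtures; recovery and coverage use 500 simulated
trials each at 120 women per cluster-period; the power cross-check runs
2,000 replicates at the design's 300; ICC recovery uses 120 replicates of
a 12-cluster wedge and 80 of the 4-cluster one; the generator's
correlation checks use a 20-cluster wedge averaged over 10 seeds. These
sizes were chosen so Monte-Carlo error is comfortably below each asserted
tolerance.

## Known limitations

* Only complete cross-sectional wedges: no incomplete designs, no closed
  cohorts, no continuous-time correlation decay.
* One working correlation family (exchangeable) plus independence; other
  small-sample corrections (Kauermann-Carroll, Fay-Graubard) are not
  implemented.
* The closed-form power treats the binary outcome on the risk-difference
  scale with a midpoint variance, the standard design-stage convention;
  its agreement with the realized log-scale GEE is at the few-point
  resolution discussed above.
* The ICC moment estimator is attenuated at very small cluster counts;
  interpret a 4-cluster ICC as a lower-ish bound, or bootstrap it.
* No multiplicity adjustment anywhere, matching the emulated analysis
  plan.
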
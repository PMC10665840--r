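---
title: "Validating lymphopenia risk models with lymphoval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating lymphopenia risk models with lymphoval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lymphoval)
```

## The problem

Radiotherapy depletes circulating lymphocytes — the most radiosensitive
cells of the hematopoietic system — and during concurrent
chemoradiotherapy (CRT) for stage III non-small cell lung cancer most
patients develop severe radiation-induced lymphopenia (RIL). Because
lymphopenia undermines consolidative immunotherapy, frozen logistic risk
scores developed in one cohort are increasingly applied in another, and
the question becomes one of *external validity*: does the score still
discriminate, and are its predicted risks calibrated, in a cohort with a
different case mix and a different a-priori event rate?

`lymphoval` packages that validation workflow end to end: scoring with
two published models (the dosimetry-based Christie model for grade ≥3
lymphopenia and the PTV-based MDACC model for grade 4), grading outcomes
from longitudinal absolute lymphocyte counts (ALC), and measuring
discrimination, calibration, and the effect of
recalibration-in-the-large.

## Outcome definition

CTCAE v5 grades lymphopenia from the on-treatment ALC nadir: grade 3 at
nadir < 0.5 K/µL, grade 4 at < 0.2 K/µL, both thresholds strict. The
nadir is the minimum ALC measured strictly after day 0 (treatment
start) and no later than the nadir window (`window_end`, by default the
last fraction day); baseline draws at day ≤ 0 are excluded, measurements
after the window are dropped with a warning, and ties in value resolve
to the earliest day. Whether counts between the last fraction and first
follow-up should enter the nadir is genuinely open in routine practice;
we default to the treatment window and expose `window_end` so either
convention is available.

## Discrimination

The c-statistic is computed as the rank-based concordance probability
(Mann–Whitney on midranks), which is exact under ties and identical to
the trapezoidal ROC AUC. No published convention fixes how its 95% CI
should be obtained in small validation cohorts; we use a stratified
bootstrap (cases and non-cases resampled separately, 2000 replicates,
percentile interval) under a fixed seed. The bootstrap count is a
tunable (`boot`); 2000 replicates put the Monte-Carlo error of the
interval endpoints well below the sampling noise of a 100-patient
cohort.

## Calibration and the intercept update

Calibration is summarised in `n_groups` contiguous risk groups of
near-equal size after ranking by predicted risk (tertiles by default,
the convention for cohorts of about 100 patients). When the cohort size
is not divisible by the group count, the remainder is assigned to the
lowest-risk groups — with 100 patients in 3 groups the sizes are
34/33/33; the choice is arbitrary but fixed and documented. Tied
predictions keep stable input order, and a constant prediction vector is
flagged degenerate rather than silently grouped.

Recalibration-in-the-large finds the intercept shift δ solving

```
Σᵢ 1 / (1 + exp(−(lpᵢ + δ))) = observed events
```

The left side is strictly increasing in δ, so the solution is unique; we
bracket it by bisection on [−50, 50] and finish with one Newton step,
accepting when the event sum matches to 1e−8. Model coefficients are
never updated — a deliberate restriction, since refitting slopes would
constitute developing a new model. Because a common shift preserves the
ranking of patients, the c-statistic is unchanged by recalibration, and
calibration-group membership is preserved while group means move; both
properties are asserted in the test suite.

Cross-grade transfer (e.g. applying the grade ≥3 Christie model to the
grade 4 incidence) is the same operation with the other outcome's event
count, via `recalibrate_intercept()`.

## The built-in models

Both models are stored as declarative `ril_model_spec` objects —
intercept, per-term coefficient and transform, and interaction terms —
and ship additionally as YAML fixtures under `inst/extdata/` that
round-trip losslessly through `read_model_spec()`. Two unit conventions
deserve note:

* **log(PTV) is the natural logarithm of the PTV in millilitres.** At
  the cohort-typical point (BMI 25.3 kg/m², PTV 337 mL) this yields a
  grade 4 risk of about 0.26, consistent with the 37% incidence in the
  model's development cohort; a base-10 logarithm would give a risk
  near 0.004, which is not credible. PTV entries expressed in litres
  must be converted before scoring.
* **Radiotherapy duration is elapsed calendar days** from first to last
  fraction inclusive: 24 fractions at 5 per week span about 32 days,
  matching the typical value for this fractionation. Whether treatment
  breaks should count is unspecified in the source model; elapsed days
  is the interpretation used throughout.

Probabilities are produced by `plogis()`, which is overflow-safe for
|log-odds| up to the double range, and `score()` refuses missing
covariates and non-positive values under a log transform rather than
imputing. The `eqd2()` helper converts a fractionation scheme to its
equivalent dose in 2 Gy fractions, `n·d·(d + α/β)/(2 + α/β)`; the
hypofractionated scheme the emulated cohort received (24 × 2.75 Gy,
α/β = 10 Gy) gives 70.1 Gy.

## The synthetic cohort generator

No patient-level data are distributed with the package, so the generator
is a first-class module: it emulates the *marginal* structure of a
stage III NSCLC CRT cohort and the statistical assumptions of the
validation, and every pipeline stage is tested against it.

* **Marginals.** Age ~ N(66.1, 8.4²) years truncated to [18, 95]; BMI ~
  N(25.3, 4.5²) kg/m² on [14, 50]. Skewed covariates are log-normal,
  parameterised from the reported median [IQR] by moment inversion
  (µ = log median; σ = log(q75/q25) / (2·Φ⁻¹(0.75))): baseline ALC 1.71
  [1.18–2.19] K/µL, PTV 337 [204–503] mL, mean heart dose 4.34
  [1.93–8.62] Gy, mean lung dose 11.1 [9.16–13.2] Gy, vertebrae V20Gy
  23.5 [14.8–32.4] % (truncated at 100). Radiotherapy duration is
  discrete on {31, 32, 33} days with probabilities (0.25, 0.5, 0.25),
  matching a median of 32 [31–33]; all patients are flagged as photon
  IMRT with concurrent chemotherapy.
* **Dependence.** A Gaussian copula couples the continuous covariates.
  True correlations in such cohorts are unreported, so the defaults are
  stated physical assumptions, exposed in `sim_config()`: larger target
  volumes push lung dose (PTV–MLD 0.6) and spine exposure (PTV–V20
  0.5), and heart and lung doses co-vary (0.4); everything else 0. The
  matrix is checked for positive definiteness.
* **Outcomes.** Linear predictors from a generating model (MDACC by
  default) are intercept-shifted via `update_intercept()` so the mean
  latent probability equals the target incidence — 78% grade ≥3 and 17%
  grade 4, the rates the package's validation scenario assumes. One
  uniform draw per patient against both shifted probabilities produces
  nested ordinal grades (grade 4 ⇒ grade ≥3 by construction, since the
  grade 4 probability is pointwise smaller).
* **Trajectories.** Grade assignment drives trajectory depth, not vice
  versa, so incidence targets are exact in expectation — a simulation
  convention, not a biological claim. Each series declines
  exponentially from baseline to a nadir level drawn uniformly inside
  the assigned grade's ALC band, on a nadir day drawn from a
  piecewise-linear quantile function with median 30 days [IQR 25–31],
  then recovers slowly (0.02/day on the log scale). Sampling is
  twice-weekly plus the nadir day, with multiplicative log-normal noise
  (σ = 0.1); noise on non-nadir days is floored just above the nadir
  level so regrading the emitted series always reproduces the assigned
  grade. In the ~0.4% of patients whose sampled baseline already lies
  inside or below the assigned band (e.g. baseline < 0.5 K/µL drawn as
  grade ≤ 2), the grade is escalated to the lowest grade the baseline
  permits, because a declining series starting there must cross the
  threshold.
* **Randomness.** One run seed drives everything; trajectories use
  per-patient sub-seeds so results are stable under reordering, and all
  generator functions restore the caller's RNG state.

What the generator does *not* emulate: covariate–outcome links other
than the generating logistic model (so validating the *other* model on
synthetic data reflects shared covariates only), real measurement
schedules with missed draws, treatment interruptions, exclusion flows,
or any mechanistic dose–lymphocyte relationship. Passing tests
therefore demonstrate the correctness of the statistical machinery under
the stated assumptions, not clinical performance on real patients.

## Numerical and design choices

* Quantiles everywhere (summary tables, bootstrap percentiles) use
  linear interpolation between order statistics (`quantile()` type 7).
* Univariable screens use maximum likelihood via `glm` with tightened
  convergence (ε = 1e−12), Wald intervals, and two-sided p-values;
  complete separation is flagged instead of reported as a huge estimate.
* Summary tables print mean ± sd for near-symmetric covariates (age,
  BMI), median [IQR] for skewed ones, and count (integer percent) for
  categoricals; full precision is retained in the numeric columns.
* Test and validation problem sizes were chosen to keep Monte-Carlo
  error far below the asserted tolerances while remaining quick:
  marginal checks at n = 20,000–40,000, incidence targeting at
  n = 100,000, shift recovery at n = 10,000, trajectory and pipeline
  checks at n = 300–8,000.

## Limitations

The two scoring rules are reproduced from their published coefficients;
any rounding in those publications propagates here. The c-statistic CI
method and the handling of the indivisible patient in "equally sized"
risk groups are unstated in the conventional workflow and fixed by the
documented choices above. The generator's correlation structure and
trajectory shape are assumptions; conclusions about model transfer to
real cohorts require real cohorts, for which `read_cohort()`/`read_alc()`
accept delimited files in the documented dialects.
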
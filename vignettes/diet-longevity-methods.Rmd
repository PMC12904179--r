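---
title: "Methods: dietary pattern scores, longevity genetics, and life expectancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dietary pattern scores, longevity genetics, and life expectancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietspan)
```

`dietspan` implements the full analysis chain used in prospective studies of
diet quality and mortality: averaged dietary assessment → pattern scores →
Cox proportional-hazards associations → gene–diet interaction → life-table
translation into years of life gained. This vignette records the models, the
assumptions behind them, and the design decisions taken where the
methodological literature leaves genuine choices open.

## Cohort construction

Participants enter the analysis with at least two completed dietary
assessments; their exposure is the arithmetic mean intake across assessments.
Exclusions are applied in a fixed, documented order — under-assessment,
implausible energy, prevalent CVD/cancer, then (for genetic analyses)
missing genotype or non-European ancestry — with sequential counts. Because
the rules are conjunctive, the retained set is order-invariant even though
the per-rule counts are not; both facts are tested.

Two decisions here were open and are package choices:

* **Energy screening** applies the sex-specific plausibility bounds
  (800–4200 kcal/day in men, 600–3500 in women) to the *mean* across
  assessments, because the averaged profile is the analysed exposure. A
  config switch (`energy_screen = "per_day"`) screens individual assessment
  days instead.
* **Missing intake values**: a food absent from a 24-hour recall is zero
  consumption and is averaged as such; a missing nutrient *total* is treated
  as genuinely missing and averaged over non-missing days. Affected rows are
  flagged.

Person-years run from the last dietary assessment to death, loss to
follow-up, or the administrative censoring date, whichever is earliest,
using 365.25-day years. Underlying-cause ICD-10 codes map to five classes
(I00–I99 cardiovascular, C00–C97 cancer, G00–G99 neurodegenerative,
J00–J99 respiratory, else other).

## Dietary pattern scores

Each index is a `scoring_spec`: a component table declaring source fields,
direction, rule, and point range. The constructor proves that component
point extremes sum to the declared index range, making range closure a
structural invariant rather than an empirical observation.

Three scoring rules exist:

* **Absolute anchors** (AHEI-2010): linear interpolation between a worst and
  a best anchor, clamped; anchors may be sex-specific (whole grains: best at
  90 g/day for men, 75 for women). The AHEI alcohol component is a tent
  function — nondrinkers receive 2.5 of 10 points, moderate intake (7 g/day
  up to 28 g/day in men, 21 in women) receives 10, and points fall linearly
  to 0 at heavy intake.
* **Cohort quintiles** (AMED, hPDI, DASH, DRRD): one to five points by rank
  within the cohort, sex-stratified only for AMED. Adverse components (red
  and processed meat, sodium, sugar-sweetened beverages, glycemic index,
  trans fat, and the animal/less-healthy plant groups of hPDI) are
  reverse-scored.
* **Ties**: average ranks, then `ceiling(5·rank/n)`; all tied values share a
  point value. This is deterministic and matches common epidemiologic
  practice; with heavily tied integer scores the resulting quintile sizes
  legitimately deviate from n/5, which the tests acknowledge explicitly.
  PRS tertiles use the identical rule with thirds.

The shipped component catalogues follow the canonical published definitions
of the five indices. Two entries deserve flagging as package assumptions:
AHEI sodium is scored against fixed anchors (1100 best, 3400 mg/day worst)
rather than cohort deciles, and the AMED alcohol component is scored by
sex-specific quintiles like every other AMED component rather than by the
original intermediate-is-best band, matching the convention that all ten
components carry 1–5 quintile points. Both are overridable by supplying a
modified `scoring_spec`. Alcohol-free variants (`spec_without_alcohol`)
shrink AHEI to 0–100 and AMED to 9–45.

## Survival models

All associations come from Cox proportional-hazards models with follow-up
time as the time scale and Efron tie handling (accurate under heavy ties;
the choice is conventional). Two covariate sets are fixed: `model1` (age,
sex) and `model2` (plus ethnicity, education, deprivation quintile,
assessment centre, smoking, physical activity, BMI class, total energy,
baseline dyslipidemia/hypertension/diabetes, PRS tertile, ten ancestry
components, genotyping batch; alcohol category added for hPDI/DASH/DRRD,
whose definitions exclude alcohol). Alcohol categories default to the
seven-level scheme (0, 0.1–5, …, >30 g/day) used in fully adjusted models;
the coarser five-level scheme is available by passing different edges.
"Unknown" is an explicit covariate level wherever it occurs — unknowns are
modelled, never dropped.

* **Trend** across quintiles: each participant's exposure is replaced by
  their quintile's median score, entered continuously; the Wald p of that
  term is the trend p.
* **Dose-response**: restricted cubic splines with three knots at the
  10th/50th/90th percentiles, in the standard normalized truncated-power
  parametrization (linear beyond the boundary knots). The curve is
  referenced to the cohort median score by default and departure from
  linearity is the Wald test on the single nonlinear coefficient.
* **Interaction with the PRS**: multiplicative interaction is a
  likelihood-ratio test between fully adjusted models with and without
  quintile × tertile product terms. Additive interaction is
  RERI = HR₁₁ − HR₁₀ − HR₀₁ + 1 with a delta-method CI from the joint
  model's coefficient covariance. The 2×2 view dichotomizes diet at the
  extreme quintiles (middle three excluded) and PRS at the extreme tertiles;
  this is a documented, configurable convention — the full 15-cell joint
  model (reference: lowest diet quintile with low PRS, the highest-risk
  combination) is retained separately.
* **Substitution models**: for each omitted food group the model includes
  all remaining groups plus total energy; holding the total fixed makes the
  coefficient of group A the log-HR of replacing the omitted group with A,
  i.e. the difference of the two groups' underlying coefficients. The tests
  verify exactly this estimand on simulated data with known food-level
  effects.
* **Cause-specific mortality** censors competing deaths at the death date
  (cause-specific hazards). A Fine–Gray adapter delegating to `cmprsk::crr`
  exists for users who want subdistribution hazards; it is clearly a
  delegation, not the primary analysis. Schoenfeld-residual diagnostics
  (`ph_diagnostic`) are reported but never gate results.

## Life-table engine

The engine converts a population life table (sex × single-year age, annual
death probability), exposure-group hazard ratios, and group prevalence by
sex and 10-year age band into group-specific life expectancy from a start
age (45 by default; 50/55/60 supported).

Numerical design choices, in decreasing order of consequence:

1. **Rates, not probabilities.** HRs multiply hazards, so probabilities are
   converted via `m = −ln(1 − q)` before scaling and back after. This keeps
   every group probability strictly below 1 for any finite HR and makes the
   prevalence-weighted group rates reproduce the population rate *exactly*
   (to machine precision; the tests require 1e-9).
2. **Reference-hazard decomposition.** The reference-group rate at each age
   solves `m_ref = m / Σ_g p_g·HR_g`. This is the unique rate satisfying
   marginal consistency when every group's hazard is proportional to the
   reference.
3. **Half-year correction** (`a_x = 0.5`): decedents contribute half a year
   in their death year — standard abridged-life-table practice.
4. **Band expansion**: 10-year prevalence bands expand to single years
   piecewise-constantly; ages outside all bands inherit the nearest band.
5. **Table close at 100**: survivorship past the final age contributes only
   its final-year term; `open_terminal = TRUE` adds an exponential
   open-ended interval `e = 1/m(100)` instead.
6. **Monte Carlo CIs** draw log-HRs independently per group from the normal
   distributions implied by each Wald CI (reference fixed at 1), recompute
   the full table per draw, and report percentile bounds. Only HR
   uncertainty is propagated — prevalence and the population life table are
   treated as fixed, which understates total uncertainty when prevalence is
   estimated from a small cohort. Draws are vectorized (prevalence matrix ×
   HR-draw matrix per sex), deterministic given the seed, and a warning is
   recorded below 100 draws.

## The synthetic cohort generator

The generator exists so that every downstream stage has a known truth. It
emulates, per participant:

* a standard-normal **latent diet-quality factor** `u`; every intake field
  is lognormal with log-location `log_mean + loading·u + between·habit`,
  where `habit` is a person-level, food-specific deviation and a further
  day-level deviation (`log_sd`) varies across assessment repeats. The
  shared factor makes beneficial foods rise together and adverse foods fall
  together, producing high inter-score correlations (about 0.7–0.9 Spearman
  between the five indices at the defaults); the food-specific habit term
  keeps the five indices imperfect, partially independent proxies of `u`.
* **genotypes** as independent binomial dosages at 19 variants with fixed
  allele frequencies and per-allele year weights calibrated so the analytic
  PRS mean is ≈17.6 years. With equal-magnitude weights the implied SD
  (≈4 years) exceeds what a realistic effect-size distribution would give —
  the calibration is qualitative, prioritizing the mean.
* **survival** from a Gompertz hazard on attained age,
  `λ(a) = α·e^{γa}·exp(β_d·u + β_g·z_PRS)`, inverted analytically from a
  unit-exponential draw; administrative censoring at 12.5 years. Defaults
  (α = 2.0e-5 men / 1.3e-5 women, γ = 0.095, β_d = log 0.92,
  β_g = log 0.95) give a middle-aged cohort (age ≈ 58, SD 8) with roughly
  4–5% deaths over a median follow-up near 11 years.
* **structural nuisances** that exercise the exclusion rules: 1–5
  assessments per participant (12% have only one), 2% implausible energy,
  3%/4% prevalent CVD/cancer, 3% missing genotypes, 5% non-European
  ancestry flags. Cause of death is drawn from a fixed mix independent of
  covariates; a hook (`cause_log_hrs`) allows cause-specific effects.

Ground truth acts on the latent factor, not on any one score, so every
score attenuates the true effect — mirroring real measurement error. The
per-SD recovery checks therefore fit the latent factor itself; fits on the
scores are expected (and observed) to attenuate.

What the generator does **not** emulate: realistic food-frequency
distributions or UK-specific portion conventions, linkage disequilibrium
between variants, time-varying diet, dependent censoring, or confounding
structure between covariates and diet (covariates are drawn independently).
Passing tests therefore demonstrate the *pipeline's* correctness under its
own assumptions, not robustness to the biases of real cohort data.

One root seed fans out to per-component child streams (demographics,
latent factor, intakes, genotypes, survival, causes), so adding a component
never perturbs the draws of another and identical seeds give byte-identical
cohorts.

## Validation strategy and problem sizes

The test suite validates each stage against an independent oracle: explicit
counting re-implementations of the rank-and-sum scorers on cohorts of ≤200,
closed-form constant-hazard life expectancy to 1e-9, the events/person-years
rate-ratio estimator for exponential survival, the published
truncated-power-basis formula for the spline, and exact RERI algebra. The
end-to-end check generates cohorts of n = 20,000, fits quintile hazard
ratios, and verifies that the Monte Carlo interval covers the life-expectancy
gain implied analytically by the generating hazard (the true group HRs are
`E[e^{βZ}|quintile]` ratios computed by numerical integration). Replicate
counts (20 for parameter recovery, 15 for end-to-end coverage, 200 for null
calibration at n = 1,000 per replicate) keep the suite deep enough for the
stated tolerances — 2% bias, ≥90% coverage, Kolmogorov–Smirnov uniformity —
while completing in about a minute; they are the package's chosen simulation
sizes, and larger runs only tighten the same checks.

## Known limitations

* Scoring anchors for AHEI follow the canonical published values; cohorts
  using different food groupings must supply their own `scoring_spec`.
* The additive-interaction convention (extreme-category dichotomization) is
  one of several defensible choices; sensitivity to it is not automated.
* The life-table CI ignores sampling error in prevalence and in the
  population life table.
* The generator's covariates are independent of diet, so `model2`
  adjustment in synthetic runs changes precision but not bias; it cannot
  demonstrate confounding control.
* Multiple imputation, time-varying covariates, and frailty models are out
  of scope.
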
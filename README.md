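# dietspan

Healthy dietary patterns, longevity genetics, and life expectancy: a tested,
reusable analysis pipeline for prospective cohort studies.

Epidemiologists studying diet and mortality typically (1) score each
participant's averaged dietary intake against several pattern indices,
(2) estimate mortality hazard ratios across index quintiles with Cox
proportional-hazards models, (3) ask whether genetic predisposition to
longevity modifies those associations, and (4) translate the hazard ratios
into something interpretable — years of life gained. `dietspan` implements
that entire chain as composable, tibble-first R functions, together with a
synthetic cohort generator with known ground truth so that every stage can be
validated end to end without access-restricted data.

## What the package computes

**Dietary pattern scores** from a declarative scoring specification
(`scoring_spec`), with shipped defaults for five canonical indices:

| Index | Components | Rule | Range |
|---|---|---|---|
| AHEI-2010 | 11 | absolute anchors, linear interpolation | 0–110 |
| AMED | 10 | sex-specific cohort quintiles | 10–50 |
| hPDI | 17 | cohort quintiles, reverse-scored animal/less-healthy plant foods | 17–85 |
| DASH | 8 | cohort quintiles | 8–40 |
| DRRD | 9 (incl. fiber, glycemic index) | cohort quintiles | 9–45 |

**A longevity polygenic risk score** as a weighted allele sum
`PRS_i = Σ_j β_j · dosage_ij`, where each β_j is the years of life gained per
effect allele, categorized into tertiles.

**Proportional-hazards associations** with follow-up time as the time scale:
quintile hazard ratios (lowest quintile as reference), trend tests by
quintile-median coding, per-SD effects, restricted cubic spline dose-response
(3 knots at the 10th/50th/90th percentiles), multiplicative (likelihood-ratio)
and additive interaction with the PRS (RERI = HR₁₁ − HR₁₀ − HR₀₁ + 1, with a
delta-method CI), a 15-cell joint diet × PRS classification, stratified
analyses, per-SD food-group effects, and leave-one-out substitution models.

**An abridged period life table** that converts population mortality, group
hazard ratios, and exposure prevalence into group-specific life expectancy.
Hazard ratios act on rates, not probabilities: with `m = −ln(1 − q)` the
reference-group rate solves `m_ref = m / Σ_g p_g·HR_g`, each group gets
`q_g = 1 − exp(−HR_g·m_ref)`, and life expectancy at a start age accumulates
`S(a)·(1 − q(a)/2)` (half-year credit in the death year) up to the table
close at age 100. Years gained is the difference to the reference group;
Monte Carlo draws over the log-HRs give percentile confidence intervals.

## Worked example

```r
library(dietspan)

cohort <- generate_cohort(simulation_params(n_participants = 5000, seed = 42))
built  <- build_analysis_cohort(cohort)
built$report
#> <exclusion_report> input: 5000 | unclassifiable: 0 | retained: 4023
#>   rule                 n_removed
#> 1 under_assessed             616
#> 2 implausible_energy          82
#> 3 prevalent_cvd_cancer       279

fit_cox(built$data, model_spec("drrd", "quintile", "model2"))
#> <hr_set> drrd (quintile, model2)
#>   level    hr    lo    hi     n n_events person_years
#> 1 Q1    1     1      1      801       89        9593.
#> 2 Q2    1.01  0.759  1.35   895      100       10666.
#> 3 Q3    0.936 0.693  1.26   808       84        9620.
#> 4 Q4    0.920 0.670  1.26   701       69        8424.
#> 5 Q5    0.735 0.536  1.01   818       69        9861.
#> p-trend: 0.0505
```

The exclusion report mirrors the standard cohort-construction funnel:
participants with fewer than two dietary assessments, implausible mean energy
intake (outside 800–4200 kcal/day in men, 600–3500 in women), or prevalent
CVD/cancer are removed before analysis. The hazard-ratio table reads like a
published results table: the top DRRD quintile has an adjusted hazard ratio
of 0.74 (0.54, 1.01) against the bottom quintile in this 5,000-person
synthetic cohort, with the per-SD effect and trend p available through
`glance()`.

The full pipeline — simulate, exclude, score, fit, life-table — runs as one
call and returns (and optionally writes) each publication-shaped table:

```r
res <- run_pipeline(pipeline_config(n_participants = 5000, seed = 42,
                                    indices = "drrd", covariates = "model2",
                                    start_ages = c(45, 60), n_draws = 300))
dplyr::filter(tibble::as_tibble(res$le_estimates), group %in% c("Q1", "Q5"))
#>   sex    group start_age    le le_lo le_hi  gain gain_lo gain_hi
#> 1 female Q1           45  40.4  39.2  42.1  0      0        0
#> 2 female Q5           45  45.4  41.7  49.2  5.02   0.747    9.09
#> 3 male   Q1           45  39.5  38.0  41.4  0      0        0
#> 4 male   Q5           45  40.7  37.3  44.2  1.20  -3.04     5.12
#> ...
```

Reading the output: at age 45, women in the top DRRD quintile of this
synthetic cohort are estimated to live 5.0 more years (95% CI 0.7–9.1) than
women in the bottom quintile; the wide intervals reflect the cohort's small
event count. `autoplot()` methods provide forest, dose-response, and
years-gained plots for each result type, and `tidy()`/`glance()` give
broom-style access to every fitted object.

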
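#' Default intake-generation parameters
#'
#' One row per intake field: lognormal location/scale on the log scale and the
#' loading of the latent healthy-diet factor. A single standard-normal latent
#' factor per participant shifts every field's log-location by its loading, so
#' beneficial foods (positive loadings) rise together while adverse foods
#' (negative loadings) fall — reproducing the moderate-to-high inter-score
#' correlations seen in real cohorts with one knob; on top of that, each
#' participant carries an independent per-food habitual-intake deviation
#' (`between_sd`, person-level, shared across assessment days) so the five
#' indices remain imperfect, partially independent proxies of the latent
#' factor. `log_sd` is the residual day-to-day (within-person) scale.
#' Medians are plausible daily intakes for a middle-aged European cohort.
#'
#' @return Tibble with `field`, `log_mean`, `log_sd`, `between_sd`,
#'   `loading`.
#' @export
default_intake_params <- function() {
  tibble::tribble(
    ~field,            ~log_mean, ~log_sd, ~between_sd, ~loading,
    "vegetables", 0.92, 0.60, 0.45, 0.30,
    "fruits", 0.69, 0.50, 0.60, 0.32,
    "fruit_juice", -0.69, 0.70, 0.60, -0.10,
    "whole_grains", 3.40, 0.60, 0.60, 0.35,
    "refined_grains", 0.41, 0.50, 0.60, -0.25,
    "legumes", -0.69, 0.60, 0.60, 0.25,
    "nuts", -0.92, 0.70, 0.60, 0.30,
    "fish", -1.05, 0.60, 0.60, 0.20,
    "poultry", -0.69, 0.50, 0.60, -0.05,
    "red_meat", -0.51, 0.50, 0.60, -0.30,
    "processed_meat", -1.05, 0.60, 0.60, -0.32,
    "eggs", -0.69, 0.50, 0.60, -0.08,
    "whole_fat_dairy", -0.22, 0.50, 0.60, -0.15,
    "low_fat_dairy", -0.22, 0.60, 0.60, 0.15,
    "potatoes", -0.22, 0.50, 0.60, -0.18,
    "ssb", -1.20, 0.80, 0.60, -0.35,
    "sweets_desserts", -0.22, 0.60, 0.60, -0.28,
    "veg_oils", -0.22, 0.50, 0.60, 0.18,
    "animal_fat", -1.20, 0.60, 0.60, -0.22,
    "tea_coffee", 1.10, 0.40, 0.60, 0.08,
    "energy_kcal", 7.60, 0.18,  0.12, 0.00,
    "fiber_g", 2.83, 0.30,  0.25, 0.35,
    "sodium_mg", 7.82, 0.25,  0.20, -0.25,
    "alcohol_g", 2.08, 0.90,  0.90, -0.05,
    "trans_fat_pct", -0.22, 0.40,  0.30, -0.25,
    "pufa_pct", 1.79, 0.25,  0.15, 0.20,
    "n3_mg", 5.01, 0.60,  0.40, 0.20,
    "glycemic_index", 4.03, 0.05, 0.04, -0.08,
    "mufa_sfa_ratio", -0.11, 0.25,  0.20, 0.15,
    "pufa_sfa_ratio", -0.60, 0.30,  0.25, 0.20
  )
}

#' Simulation parameters for the synthetic cohort generator
#'
#' Ground-truth parameters of the data-generating process. Survival times
#' follow a Gompertz hazard on attained age,
#' `lambda(a) = alpha * exp(gamma * a) * exp(bd * z_diet + bg * z_prs)`,
#' where `z_diet` is the standard-normal latent diet factor and `z_prs` the
#' analytically standardized polygenic score; administrative censoring is
#' applied at `admin_censor_years`. Defaults emulate a middle-aged European
#' volunteer cohort: baseline age about 58 (SD 8), roughly 4-5% deaths over
#' a median follow-up near 11 years, and a per-SD diet hazard ratio of 0.92.
#'
#' @param n_participants Cohort size.
#' @param seed Root seed; per-component child streams are derived from it.
#' @param intake_params Tibble as [default_intake_params()].
#' @param n_snps,maf,snp_weights Longevity variant panel: allele frequencies
#'   in (0,1) and per-allele weights in years of life gained. Defaults give
#'   an analytic PRS mean of about 17.6 years.
#' @param baseline_hazard Named list of per-sex Gompertz `c(alpha, gamma)`.
#' @param log_hr_per_sd_diet,log_hr_per_sd_prs Ground-truth log hazard ratios
#'   per SD of the latent diet factor / the PRS.
#' @param admin_censor_years Administrative censoring horizon (years).
#' @param cause_mix Named probabilities over cause classes, summing to 1.
#' @param assessment_probs Probabilities of completing 1..5 dietary
#'   assessments (participants with one assessment exercise the exclusions).
#' @param implausible_energy_frac Fraction of participants given implausible
#'   energy intakes (half inflated, half deflated).
#' @param prevalent_cvd_frac,prevalent_cancer_frac Prevalent-disease flags at
#'   baseline.
#' @param genetic_missing_frac Fraction without genotype data.
#' @param non_european_frac Fraction flagged non-European ancestry.
#' @param n_centres Number of assessment centres.
#' @param age_mean,age_sd,age_range Baseline age distribution (normal,
#'   truncated to `age_range`).
#' @param cause_log_hrs Optional named list of per-cause log-HR overrides for
#'   the diet factor (hook for cause-specific effects); `NULL` assigns cause
#'   independently of covariates.
#' @return A validated `simulation_params` object.
#' @export
simulation_params <- function(
    n_participants = 5000,
    seed = 1L,
    intake_params = default_intake_params(),
    n_snps = 19L,
    maf = round(seq(0.12, 0.48, length.out = n_snps), 3),
    snp_weights = round(seq(0.6, 2.5, length.out = n_snps) *
                          (17.6 / sum(2 * seq(0.6, 2.5, length.out = n_snps) *
                                        round(seq(0.12, 0.48, length.out = n_snps), 3))), 4),
    baseline_hazard = list(male = c(alpha = 2.0e-5, gamma = 0.095),
                           female = c(alpha = 1.3e-5, gamma = 0.095)),
    log_hr_per_sd_diet = log(0.92),
    log_hr_per_sd_prs = log(0.95),
    admin_censor_years = 12.5,
    cause_mix = c(cvd = 0.22, cancer = 0.45, neurodegenerative = 0.08,
                  respiratory = 0.07, other = 0.18),
    assessment_probs = c(0.12, 0.28, 0.27, 0.20, 0.13),
    implausible_energy_frac = 0.02,
    prevalent_cvd_frac = 0.03,
    prevalent_cancer_frac = 0.04,
    genetic_missing_frac = 0.03,
    non_european_frac = 0.05,
    n_centres = 8L,
    age_mean = 58, age_sd = 8, age_range = c(40, 70),
    cause_log_hrs = NULL) {
  p <- list(
    n_participants = n_participants, seed = seed, intake_params = intake_params,
    n_snps = n_snps, maf = maf, snp_weights = snp_weights,
    baseline_hazard = baseline_hazard,
    log_hr_per_sd_diet = log_hr_per_sd_diet,
    log_hr_per_sd_prs = log_hr_per_sd_prs,
    admin_censor_years = admin_censor_years, cause_mix = cause_mix,
    assessment_probs = assessment_probs,
    implausible_energy_frac = implausible_energy_frac,
    prevalent_cvd_frac = prevalent_cvd_frac,
    prevalent_cancer_frac = prevalent_cancer_frac,
    genetic_missing_frac = genetic_missing_frac,
    non_european_frac = non_european_frac,
    n_centres = n_centres, age_mean = age_mean, age_sd = age_sd,
    age_range = age_range, cause_log_hrs = cause_log_hrs
  )
  validate_simulation_params(p)
  structure(p, class = "simulation_params")
}

validate_simulation_params <- function(p) {
  fail <- function(field, why) {
    abort(paste0("Invalid simulation parameter `", field, "`: ", why))
  }
  if (!is.numeric(p$n_participants) || p$n_participants < 1) {
    fail("n_participants", "must be >= 1.")
  }
  if (length(p$maf) != p$n_snps) fail("maf", "length must equal n_snps.")
  if (any(p$maf < 0 | p$maf >= 1)) fail("maf", "all values must lie in [0, 1).")
  if (length(p$snp_weights) != p$n_snps) fail("snp_weights", "length must equal n_snps.")
  if (any(!is.finite(p$snp_weights))) fail("snp_weights", "must be finite.")
  for (s in names(p$baseline_hazard)) {
    bh <- p$baseline_hazard[[s]]
    if (bh[["alpha"]] <= 0) fail("baseline_hazard", paste0(s, ": alpha must be > 0."))
    if (bh[["gamma"]] < 0) fail("baseline_hazard", paste0(s, ": gamma must be >= 0."))
  }
  if (abs(sum(p$cause_mix) - 1) > 1e-9) fail("cause_mix", "must sum to 1.")
  if (any(p$cause_mix < 0)) fail("cause_mix", "probabilities must be >= 0.")
  if (length(p$assessment_probs) != 5 || abs(sum(p$assessment_probs) - 1) > 1e-9) {
    fail("assessment_probs", "must be 5 probabilities summing to 1.")
  }
  if (p$admin_censor_years <= 0) fail("admin_censor_years", "must be > 0.")
  invisible(p)
}

#' Analytic mean and SD of the polygenic score implied by the panel
#'
#' Binomial genotype moments: dosage at SNP j is Binomial(2, maf_j), so the
#' weighted sum has mean `sum(2 w p)` and variance `sum(w^2 2 p (1-p))`.
#'
#' @param maf,weights Allele frequencies and per-allele weights.
#' @return Named numeric `c(mean, sd)`.
#' @export
prs_analytic_moments <- function(maf, weights) {
  c(mean = sum(2 * weights * maf),
    sd = sqrt(sum(weights^2 * 2 * maf * (1 - maf))))
}

# inverse-CDF draw from a Gompertz hazard alpha*exp(gamma*(a0+t))*rr
draw_gompertz_time <- function(n, alpha, gamma, age0, rr) {
  e <- rexp(n)
  if (gamma > 0) {
    log1p(gamma * e / (alpha * exp(gamma * age0) * rr)) / gamma
  } else {
    e / (alpha * rr)
  }
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws correlated food-group and nutrient intakes from the latent-factor
#' lognormal model, binomial genotype dosages, demographics and covariates,
#' and Gompertz survival with a log-linear hazard in the latent diet factor
#' and the standardized polygenic score, administratively censored. A small
#' configurable fraction of participants receives implausible energy values,
#' prevalent-disease flags, missing genotypes, or non-European ancestry so
#' the exclusion rules have work to do. Deterministic given the seed; each
#' component draws from its own child stream.
#'
#' @param params A [simulation_params()] object.
#' @return A `synthetic_cohort`: list with `intakes` (participant x
#'   assessment rows, one column per intake field), `genotypes` (participant
#'   x SNP dosages, genotyped subset only), `snp_weights` (panel table),
#'   `participants` (demographics, covariates, ground-truth `diet_factor`,
#'   `time_years`, `event`, `cause`), and `params` (the ground truth).
#' @export
generate_cohort <- function(params = simulation_params()) {
  if (!inherits(params, "simulation_params")) {
    params <- do.call(simulation_params, params)
  }
  validate_simulation_params(params)
  n <- as.integer(params$n_participants)
  id <- sprintf("P%05d", seq_len(n))

  demo <- with_stream_seed(params$seed, "demographics", {
    age <- pmin(pmax(rnorm(n, params$age_mean, params$age_sd),
                     params$age_range[1]), params$age_range[2])
    tibble(
      participant_id = id,
      sex = sample(c("male", "female"), n, replace = TRUE, prob = c(0.44, 0.56)),
      age = age,
      ethnicity = sample(c("white", "not_white"), n, TRUE, prob = c(0.94, 0.06)),
      education = sample(c("lower_secondary", "upper_secondary", "vocational",
                           "college_university", "other"), n, TRUE,
                         prob = c(0.15, 0.2, 0.15, 0.42, 0.08)),
      deprivation_q = sample(1:5, n, TRUE),
      centre = sample(seq_len(params$n_centres), n, TRUE),
      smoking = sample(c("never", "former", "current"), n, TRUE,
                       prob = c(0.56, 0.35, 0.09)),
      activity = sample(c("<600", "600-1199", ">=1200", "unknown"), n, TRUE,
                        prob = c(0.25, 0.22, 0.60, 0.08)),
      bmi_class = sample(c("<25", "25-29.9", ">=30", "unknown"), n, TRUE,
                         prob = c(0.40, 0.40, 0.18, 0.02)),
      dyslipidemia = rbinom(n, 1, 0.25) == 1,
      hypertension = rbinom(n, 1, 0.30) == 1,
      diabetes = rbinom(n, 1, 0.05) == 1,
      batch = sample(1:3, n, TRUE),
      european_ancestry = runif(n) > params$non_european_frac,
      prevalent_cvd = runif(n) < params$prevalent_cvd_frac,
      prevalent_cancer = runif(n) < params$prevalent_cancer_frac
    )
  })
  pcs <- with_stream_seed(params$seed, "ancestry_pcs", {
    m <- matrix(rnorm(n * 10), nrow = n)
    colnames(m) <- paste0("pc", 1:10)
    as_tibble(m)
  })
  demo <- bind_cols(demo, pcs)

  u <- with_stream_seed(params$seed, "latent_diet", rnorm(n))

  ip <- params$intake_params
  intakes <- with_stream_seed(params$seed, "intakes", {
    n_assess <- sample(1:5, n, replace = TRUE, prob = params$assessment_probs)
    rows <- rep(seq_len(n), n_assess)
    assess <- sequence(n_assess)
    m <- matrix(NA_real_, nrow = length(rows), ncol = nrow(ip))
    colnames(m) <- ip$field
    habit <- matrix(rnorm(n * nrow(ip)), nrow = n)  # person-level food deviations
    for (j in seq_len(nrow(ip))) {
      m[, j] <- exp(ip$log_mean[j] + ip$loading[j] * u[rows] +
                      ip$between_sd[j] * habit[rows, j] +
                      rnorm(length(rows), 0, ip$log_sd[j]))
    }
    bind_cols(
      tibble(participant_id = id[rows], assessment = assess),
      as_tibble(m)
    )
  })

  # implausible-energy artifacts: inflate half, deflate half, all assessments
  intakes <- with_stream_seed(params$seed, "energy_artifacts", {
    n_bad <- if ("energy_kcal" %in% names(intakes)) {
      floor(params$implausible_energy_frac * n)
    } else 0L
    if (n_bad > 0) {
      bad <- sample(id, n_bad)
      hi <- bad[seq_len(ceiling(n_bad / 2))]
      lo <- setdiff(bad, hi)
      intakes$energy_kcal[intakes$participant_id %in% hi] <- runif(
        sum(intakes$participant_id %in% hi), 4400, 5200)
      intakes$energy_kcal[intakes$participant_id %in% lo] <- runif(
        sum(intakes$participant_id %in% lo), 300, 520)
    }
    intakes
  })

  geno <- with_stream_seed(params$seed, "genotypes", {
    g <- vapply(params$maf, function(p) rbinom(n, 2L, p), integer(n))
    colnames(g) <- sprintf("snp%02d", seq_len(params$n_snps))
    has_geno <- runif(n) > params$genetic_missing_frac
    bind_cols(tibble(participant_id = id), as_tibble(g))[has_geno, ]
  })
  weights_tbl <- tibble(
    snp_id = sprintf("snp%02d", seq_len(params$n_snps)),
    effect_allele = rep(c("A", "C", "G", "T"), length.out = params$n_snps),
    weight = params$snp_weights
  )

  mom <- prs_analytic_moments(params$maf, params$snp_weights)
  prs_all <- as.matrix(dplyr::select(
    dplyr::left_join(tibble(participant_id = id), geno, by = "participant_id"),
    -"participant_id"
  )) %*% params$snp_weights
  z_prs <- if (mom[["sd"]] > 0) {
    (as.numeric(prs_all) - mom[["mean"]]) / mom[["sd"]]
  } else {
    numeric(n)  # monomorphic panel: no genetic variation in hazard
  }
  z_prs[is.na(z_prs)] <- 0  # ungenotyped: population-average genetic hazard

  surv <- with_stream_seed(params$seed, "survival", {
    rr <- exp(params$log_hr_per_sd_diet * u + params$log_hr_per_sd_prs * z_prs)
    t <- numeric(n)
    for (s in names(params$baseline_hazard)) {
      idx <- demo$sex == s
      bh <- params$baseline_hazard[[s]]
      t[idx] <- draw_gompertz_time(sum(idx), bh[["alpha"]], bh[["gamma"]],
                                   demo$age[idx], rr[idx])
    }
    event <- t <= params$admin_censor_years
    tibble(
      time_years = pmin(t, params$admin_censor_years),
      event = event
    )
  })
  cause <- with_stream_seed(params$seed, "cause", {
    cl <- rep(NA_character_, n)
    if (any(surv$event)) {
      cl[surv$event] <- sample(names(params$cause_mix), sum(surv$event),
                               replace = TRUE, prob = params$cause_mix)
    }
    cl
  })

  participants <- demo |>
    mutate(diet_factor = u, prs_true_z = z_prs) |>
    bind_cols(surv) |>
    mutate(cause = cause)

  structure(
    list(intakes = intakes, genotypes = geno, snp_weights = weights_tbl,
         participants = participants, params = params),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$participants), " participants, ",
      nrow(x$intakes), " assessment rows, ",
      sum(x$participants$event), " deaths\n", sep = "")
  invisible(x)
}

#' Generate a synthetic population life table
#'
#' Single-year death probabilities from a Gompertz mortality law per sex:
#' `q(a) = 1 - exp(-alpha * exp(gamma * a))`. Stands in for national sex- and
#' age-specific population mortality rates.
#'
#' @param gompertz Named list of per-sex `c(alpha, gamma)`.
#' @param ages Integer ages covered (single years).
#' @return Tibble with `sex`, `age`, `qx`, probabilities in (0, 1) and
#'   nondecreasing in age when `gamma >= 0`.
#' @export
generate_population_life_table <- function(
    gompertz = list(male = c(alpha = 4e-5, gamma = 0.085),
                    female = c(alpha = 2.4e-5, gamma = 0.088)),
    ages = 0:100) {
  purrr::map_dfr(names(gompertz), function(s) {
    g <- gompertz[[s]]
    if (g[["alpha"]] <= 0) abort("Gompertz alpha must be > 0.")
    q <- 1 - exp(-g[["alpha"]] * exp(g[["gamma"]] * ages))
    if (any(q >= 1)) {
      abort("Death probability reaches 1 within the age range; reduce alpha or gamma.")
    }
    tibble(sex = s, age = as.integer(ages), qx = q)
  })
}
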
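#' Per-SD food-group associations and food-score correlations
#'
#' One Cox fit per food group with the stated covariate set, the averaged
#' food intake entered continuously per SD increment, plus the Spearman
#' correlation matrix between the food groups and the five dietary scores.
#'
#' @param data Analysis cohort tibble (must contain the food columns, e.g.
#'   via joining the averaged profiles).
#' @param food_groups Character vector of food columns.
#' @param covariates Covariate set id.
#' @param score_cols Score columns for the correlation matrix.
#' @return List with `effects` (tibble: food, per-SD HR/CI, sd used) and
#'   `correlations` (food x score Spearman matrix).
#' @export
food_group_effects <- function(data, food_groups,
                               covariates = "model2",
                               score_cols = c("ahei", "amed", "hpdi", "dash", "drrd")) {
  stop_missing_fields(data, food_groups, "analysis cohort")
  covs <- covariate_terms(covariates, index = NULL)
  effects <- purrr::map_dfr(food_groups, function(fg) {
    s <- sd(data[[fg]])
    if (s == 0) abort(paste0("Food group '", fg, "' is constant."))
    data$..x <- (data[[fg]] - mean(data[[fg]])) / s
    fit <- fit_coxph(cox_formula("..x", covs), data)
    hr_row(fit, "^\\.\\.x") |>
      mutate(food = fg, sd = s, .before = 1) |>
      dplyr::select(-"term")
  })
  sc <- intersect(score_cols, names(data))
  correlations <- if (length(sc)) {
    stats::cor(as.matrix(data[food_groups]), as.matrix(data[sc]),
               method = "spearman")
  } else NULL
  list(effects = effects, correlations = correlations)
}

#' Leave-one-out substitution models across food groups
#'
#' For each omitted food group the model contains all remaining groups plus
#' total energy intake (and the covariate set); because total intake is held
#' fixed, the coefficient of group A estimates the effect of replacing the
#' omitted group with A. Rows of the returned matrix are the omitted group,
#' columns the replacement.
#'
#' @param data Analysis cohort tibble with per-SD-comparable food columns.
#' @param food_groups Character vector (>= 2) of food columns.
#' @param covariates Covariate set id.
#' @return List with `hr_matrix` (omitted x replacement substitution HRs)
#'   and `detail` (long tibble with CIs).
#' @export
leave_one_out_substitution <- function(data, food_groups, covariates = "model1") {
  if (length(food_groups) < 2) abort("Need at least two food groups to substitute.")
  stop_missing_fields(data, food_groups, "analysis cohort")
  covs <- covariate_terms(covariates, index = NULL)
  scaled <- data
  for (fg in food_groups) {
    scaled[[paste0("..z_", fg)]] <- as.numeric(scale(data[[fg]]))
  }
  detail <- purrr::map_dfr(food_groups, function(omit) {
    others <- setdiff(food_groups, omit)
    terms <- paste0("..z_", others)
    fit <- fit_coxph(cox_formula(c(terms, "energy_kcal"), covs), scaled)
    if (anyNA(coef(fit)[terms])) {
      abort("Collinear food-group totals; drop the total-intake term or a group.")
    }
    hr_row(fit, "^\\.\\.z_") |>
      mutate(omitted = omit,
             replacement = stringr::str_remove(.data$term, "^\\.\\.z_"),
             .before = 1) |>
      dplyr::select(-"term")
  })
  hr_matrix <- detail |>
    dplyr::select("omitted", "replacement", "hr") |>
    tidyr::pivot_wider(names_from = "replacement", values_from = "hr") |>
    tibble::column_to_rownames("omitted") |>
    as.matrix()
  list(hr_matrix = hr_matrix[food_groups, , drop = FALSE], detail = detail)
}

#' Cause-specific mortality fit
#'
#' Deaths from other causes are censored at the death date (cause-specific
#' hazards); otherwise identical to the all-cause fit.
#'
#' @param data Analysis cohort tibble with a `cause` column.
#' @param cause One of `cvd`, `cancer`, `neurodegenerative`, `respiratory`,
#'   `other`.
#' @param spec A [model_spec()].
#' @return An `hr_set`.
#' @export
cause_specific_fit <- function(data, cause, spec) {
  known <- c("cvd", "cancer", "neurodegenerative", "respiratory", "other")
  if (!cause %in% known) {
    abort(paste0("Unknown cause class '", cause, "'; expected one of ",
                 paste(known, collapse = ", "), "."))
  }
  stop_missing_fields(data, "cause", "analysis cohort")
  data$event <- data$event & !is.na(data$cause) & data$cause == cause
  fit_cox(data, spec)
}

#' Fine-Gray competing-risks adapter
#'
#' Optional delegation to an established subdistribution-hazard routine
#' ([cmprsk::crr()]) for users who want the competing-risks refit; the
#' cause-specific censoring approach above remains the primary analysis.
#'
#' @param data Analysis cohort tibble with `cause`.
#' @param cause Cause of interest.
#' @param index Score column; entered per SD.
#' @return Tibble with the per-SD subdistribution HR and CI.
#' @export
fine_gray_adapter <- function(data, cause, index) {
  if (!requireNamespace("cmprsk", quietly = TRUE)) {
    abort("Package 'cmprsk' is required for the Fine-Gray adapter.")
  }
  stop_missing_fields(data, c("cause", index), "analysis cohort")
  status <- ifelse(!data$event, 0L, ifelse(data$cause == cause, 1L, 2L))
  x <- as.matrix(scale(data[[index]]))
  colnames(x) <- "per_sd"
  fit <- cmprsk::crr(ftime = data$time_years, fstatus = status, cov1 = x)
  s <- summary(fit)
  tibble(
    index = index, cause = cause,
    hr = unname(s$conf.int[1, "exp(coef)"]),
    lo = unname(s$conf.int[1, 3]), hi = unname(s$conf.int[1, 4])
  )
}
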
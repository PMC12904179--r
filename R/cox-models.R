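#' Covariate sets for the Cox models
#'
#' `model1` adjusts for age (continuous) and sex. `model2` additionally
#' adjusts for ethnicity, education, deprivation quintile, assessment centre,
#' smoking, physical activity, BMI class, total energy, baseline
#' dyslipidemia/hypertension/diabetes, PRS tertile, the 10 ancestry
#' components, and genotyping batch; for indices without an alcohol component
#' (hPDI, DASH, DRRD) alcohol category is added on top.
#'
#' @param set `"model1"` or `"model2"`.
#' @param index Dietary index name (decides the alcohol adjustment).
#' @param drop Covariate terms to remove (e.g. the stratification variable in
#'   stratified analyses, or `prs_tertile` when PRS is the exposure).
#' @return Character vector of model terms.
#' @export
covariate_terms <- function(set = c("model1", "model2"), index = NULL,
                            drop = character()) {
  set <- match.arg(set)
  terms <- c("age", "sex")
  if (set == "model2") {
    terms <- c(terms, "ethnicity", "education", "factor(deprivation_q)",
               "factor(centre)", "smoking", "activity", "bmi_class",
               "energy_kcal", "dyslipidemia", "hypertension", "diabetes",
               "prs_tertile", paste0("pc", 1:10), "batch")
    if (!is.null(index) && index %in% c("hpdi", "dash", "drrd")) {
      terms <- c(terms, "alcohol_cat")
    }
  }
  setdiff(terms, drop)
}

#' Specification of one exposure-mortality Cox model
#'
#' @param index Score column name (e.g. `"drrd"`), or a food-group field.
#' @param exposure `"quintile"` (categorical, lowest quintile reference),
#'   `"per_sd"` (continuous, standardized), or `"continuous"` (raw scale).
#' @param covariates `"model1"` or `"model2"`.
#' @param drop_covariates Terms to remove from the covariate set.
#' @return `model_spec` list.
#' @export
model_spec <- function(index, exposure = c("quintile", "per_sd", "continuous"),
                       covariates = c("model2", "model1"),
                       drop_covariates = character()) {
  structure(
    list(index = index, exposure = match.arg(exposure),
         covariates = match.arg(covariates),
         drop_covariates = drop_covariates),
    class = "model_spec"
  )
}

cox_formula <- function(exposure_term, covs) {
  stats::as.formula(paste(
    "survival::Surv(time_years, event) ~", paste(c(exposure_term, covs), collapse = " + ")
  ))
}

fit_coxph <- function(formula, data) {
  fit <- withCallingHandlers(
    survival::coxph(formula, data = data, ties = "efron", model = TRUE),
    warning = function(w) {
      if (grepl("did not converge|beta may be infinite", conditionMessage(w))) {
        abort(paste0("Cox model failed to converge cleanly: ",
                     conditionMessage(w)))
      }
    }
  )
  fit
}

hr_row <- function(fit, term_pattern, conf = 0.95) {
  co <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  keep <- grepl(term_pattern, names(co), fixed = FALSE)
  z <- qnorm(1 - (1 - conf) / 2)
  tibble(
    term = names(co)[keep],
    log_hr = unname(co[keep]),
    se = unname(se[keep]),
    hr = exp(unname(co[keep])),
    lo = exp(unname(co[keep]) - z * unname(se[keep])),
    hi = exp(unname(co[keep]) + z * unname(se[keep]))
  )
}

#' Fit a proportional-hazards model for one exposure
#'
#' Partial-likelihood point estimates with Efron tie handling and Wald
#' confidence intervals; follow-up time is the time scale. For quintile
#' exposures the lowest quintile is the reference, every level must contain
#' at least one event, and the returned set also carries the per-SD effect
#' and the median-coded trend p so one call reproduces a full results-table
#' row.
#'
#' @param data Analysis cohort tibble (`time_years`, `event`, exposure and
#'   covariate columns; quintile exposures expect `<index>_q`).
#' @param spec A [model_spec()].
#' @return An object of class `hr_set`: exposure-level HRs with events and
#'   person-years, per-SD HR, trend p, and the underlying `coxph` fit.
#' @export
fit_cox <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  covs <- covariate_terms(spec$covariates, spec$index, spec$drop_covariates)
  idx <- spec$index

  if (spec$exposure == "quintile") {
    qcol <- paste0(idx, "_q")
    stop_missing_fields(data, c(qcol, "time_years", "event"), "analysis cohort")
    data$..q <- factor(data[[qcol]], levels = sort(unique(data[[qcol]])))
    ev <- data |>
      group_by(.data$..q) |>
      summarise(n = dplyr::n(), n_events = sum(.data$event),
                person_years = sum(.data$time_years), .groups = "drop")
    if (any(ev$n_events == 0)) {
      abort(paste0("Zero events in exposure level(s) ",
                   paste(ev$..q[ev$n_events == 0], collapse = ", "),
                   "; merge levels or enlarge the cohort."))
    }
    fit <- fit_coxph(cox_formula("..q", covs), data)
    rows <- hr_row(fit, "^\\.\\.q")
    levels_tbl <- tibble(
      level = paste0("Q", levels(data$..q)),
      hr = c(1, rows$hr), lo = c(1, rows$lo), hi = c(1, rows$hi),
      log_hr = c(0, rows$log_hr), se = c(0, rows$se)
    ) |>
      bind_cols(dplyr::select(ev, "n", "n_events", "person_years"))
    per_sd <- fit_cox(data, model_spec(idx, "per_sd", spec$covariates,
                                       spec$drop_covariates))
    trend <- trend_test(data, idx, covariates = spec$covariates,
                        drop_covariates = spec$drop_covariates)
    structure(
      list(index = idx, exposure = "quintile", levels = levels_tbl,
           per_sd = per_sd$levels, p_trend = trend$p, fit = fit,
           covariates = spec$covariates),
      class = "hr_set"
    )
  } else {
    stop_missing_fields(data, c(idx, "time_years", "event"), "analysis cohort")
    x <- data[[idx]]
    data$..x <- if (spec$exposure == "per_sd") (x - mean(x)) / sd(x) else x
    fit <- fit_coxph(cox_formula("..x", covs), data)
    rows <- hr_row(fit, "^\\.\\.x") |>
      mutate(term = if (spec$exposure == "per_sd") "per_sd" else idx) |>
      rename(level = "term") |>
      mutate(n = nrow(data), n_events = sum(data$event),
             person_years = sum(data$time_years))
    structure(
      list(index = idx, exposure = spec$exposure, levels = rows,
           per_sd = NULL, p_trend = NULL, fit = fit,
           covariates = spec$covariates),
      class = "hr_set"
    )
  }
}

#' @export
print.hr_set <- function(x, ...) {
  cat("<hr_set> ", x$index, " (", x$exposure, ", ", x$covariates, ")\n", sep = "")
  print(dplyr::select(x$levels, dplyr::any_of(
    c("level", "hr", "lo", "hi", "n", "n_events", "person_years"))))
  if (!is.null(x$p_trend)) cat("p-trend:", format(signif(x$p_trend, 3)), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a hazard-ratio set into one row per exposure level
#' @param x An `hr_set`.
#' @param ... Unused.
#' @method tidy hr_set
#' @export
tidy.hr_set <- function(x, ...) {
  x$levels |> mutate(index = x$index, exposure = x$exposure, .before = 1)
}

#' One-row model summary for a hazard-ratio set
#' @param x An `hr_set`.
#' @param ... Unused.
#' @method glance hr_set
#' @export
glance.hr_set <- function(x, ...) {
  tibble(
    index = x$index, exposure = x$exposure, covariates = x$covariates,
    n = sum(x$levels$n %||% NA), n_events = sum(x$levels$n_events %||% NA),
    p_trend = x$p_trend %||% NA_real_,
    per_sd_hr = if (!is.null(x$per_sd)) x$per_sd$hr[1] else NA_real_,
    concordance = unname(x$fit$concordance["concordance"])
  )
}

#' Trend test across score quintiles by median coding
#'
#' Each participant's exposure is replaced by the median score of their
#' quintile and entered as a continuous term; the Wald p of that term is the
#' trend p.
#'
#' @param data Analysis cohort tibble with `<index>` and `<index>_q`.
#' @param index Score column name.
#' @param covariates,drop_covariates As in [model_spec()].
#' @return List with `p`, `log_hr`, `se`, and the quintile-median `coding`.
#' @export
trend_test <- function(data, index, covariates = "model2",
                       drop_covariates = character()) {
  qcol <- paste0(index, "_q")
  stop_missing_fields(data, c(index, qcol), "analysis cohort")
  coding <- data |>
    group_by(q = .data[[qcol]]) |>
    summarise(median_score = median(.data[[index]]), .groups = "drop")
  data$..trend <- coding$median_score[match(data[[qcol]], coding$q)]
  covs <- covariate_terms(covariates, index, drop_covariates)
  fit <- fit_coxph(cox_formula("..trend", covs), data)
  b <- coef(fit)[["..trend"]]
  se <- sqrt(vcov(fit)["..trend", "..trend"])
  list(p = 2 * stats::pnorm(-abs(b / se)), log_hr = b, se = se, coding = coding)
}

#' Restricted cubic spline basis (3+ knots, Harrell parametrization)
#'
#' Returns the linear column plus `k - 2` nonlinear columns
#' `((x-t_j)+^3 - (x-t_{k-1})+^3 (t_k-t_j)/(t_k-t_{k-1})
#'   + (x-t_k)+^3 (t_{k-1}-t_j)/(t_k-t_{k-1})) / (t_k-t_1)^2`,
#' which is linear beyond the boundary knots.
#'
#' @param x Numeric vector.
#' @param knots Increasing knot locations (length >= 3).
#' @return Matrix with `length(knots) - 1` columns.
#' @export
rcs_basis <- function(x, knots) {
  k <- length(knots)
  if (k < 3) abort("Restricted cubic splines need at least 3 knots.")
  if (is.unsorted(knots, strictly = TRUE)) abort("Knots must be strictly increasing.")
  pos3 <- function(u) pmax(u, 0)^3
  tk <- knots[k]; tk1 <- knots[k - 1]
  norm <- (knots[k] - knots[1])^2
  nl <- vapply(seq_len(k - 2), function(j) {
    (pos3(x - knots[j]) -
       pos3(x - tk1) * (tk - knots[j]) / (tk - tk1) +
       pos3(x - tk) * (tk1 - knots[j]) / (tk - tk1)) / norm
  }, numeric(length(x)))
  out <- cbind(x, nl)
  colnames(out) <- c("lin", paste0("nl", seq_len(k - 2)))
  out
}

#' Spline dose-response curve for a dietary score
#'
#' Restricted cubic spline with three knots at the 10th, 50th, and 90th
#' percentiles of the score; the curve is referenced to a stated score value
#' (default the cohort median) and departure from linearity is the Wald test
#' on the nonlinear coefficient.
#'
#' @param data Analysis cohort tibble.
#' @param index Score column name.
#' @param covariates Covariate set id.
#' @param ref_value Score value the curve is referenced to.
#' @param grid_n Number of grid points across the observed score range.
#' @return List of class `spline_dr`: `curve` (tibble `score`, `log_hr`,
#'   `lo`, `hi`), `p_nonlinear`, `knots`, `ref_value`, `fit`.
#' @export
spline_dose_response <- function(data, index, covariates = "model2",
                                 ref_value = NULL, grid_n = 100) {
  stop_missing_fields(data, c(index, "time_years", "event"), "analysis cohort")
  x <- data[[index]]
  knots <- unname(quantile(x, c(0.1, 0.5, 0.9)))
  if (length(unique(knots)) < 3) abort("Degenerate knots: score distribution too discrete.")
  ref_value <- ref_value %||% median(x)
  basis <- rcs_basis(x, knots)
  data$..s1 <- basis[, 1]; data$..s2 <- basis[, 2]
  covs <- covariate_terms(covariates, index)
  fit <- fit_coxph(cox_formula(c("..s1", "..s2"), covs), data)
  b <- coef(fit)[c("..s1", "..s2")]
  V <- vcov(fit)[c("..s1", "..s2"), c("..s1", "..s2")]
  p_nl <- 2 * stats::pnorm(-abs(b[2] / sqrt(V[2, 2])))
  grid <- seq(min(x), max(x), length.out = grid_n)
  bg <- rcs_basis(grid, knots)
  br <- rcs_basis(ref_value, knots)
  d <- sweep(bg, 2, br)      # basis difference to the reference value
  log_hr <- as.numeric(d %*% b)
  se <- sqrt(rowSums((d %*% V) * d))
  structure(
    list(
      curve = tibble(score = grid, log_hr = log_hr,
                     lo = log_hr - qnorm(0.975) * se,
                     hi = log_hr + qnorm(0.975) * se),
      p_nonlinear = unname(p_nl), knots = knots, ref_value = ref_value,
      index = index, fit = fit
    ),
    class = "spline_dr"
  )
}

#' @export
print.spline_dr <- function(x, ...) {
  cat("<spline_dr> ", x$index, ": knots at ",
      paste(signif(x$knots, 4), collapse = "/"),
      ", nonlinearity p = ", format(signif(x$p_nonlinear, 3)), "\n", sep = "")
  invisible(x)
}

#' Schoenfeld residual proportional-hazards diagnostic
#'
#' Thin delegation to [survival::cox.zph()]; reported, never gating.
#'
#' @param hr_set An `hr_set`.
#' @return The `cox.zph` table as a tibble.
#' @export
ph_diagnostic <- function(hr_set) {
  z <- survival::cox.zph(hr_set$fit)
  as_tibble(z$table, rownames = "term")
}
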
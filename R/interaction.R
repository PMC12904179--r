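#' Multiplicative and additive diet-by-genetics interaction
#'
#' Multiplicative interaction: likelihood-ratio test between fully adjusted
#' models with and without score-quintile x PRS-tertile product terms.
#' Additive interaction: the relative excess risk due to interaction,
#' `RERI = HR11 - HR10 - HR01 + 1`, computed from a joint model of the
#' dichotomized exposures (diet top vs bottom quintile, middle quintiles
#' excluded; PRS high vs low tertile, intermediate excluded) with a
#' delta-method confidence interval from the coefficient covariance. PRS
#' tertile is removed from the covariate set because PRS is an exposure here.
#' Stratum-specific quintile HR sets by PRS tertile are attached.
#'
#' @param data Analysis cohort tibble.
#' @param index Score column name.
#' @param covariates Covariate set id.
#' @param strata_fits Also fit per-PRS-tertile quintile HR sets (slower).
#' @return `interaction_result`: `p_multiplicative`, `reri`
#'   (estimate/lo/hi), the three joint HRs, and `by_prs` stratum fits.
#' @export
interaction_analysis <- function(data, index, covariates = "model2",
                                 strata_fits = TRUE) {
  qcol <- paste0(index, "_q")
  stop_missing_fields(data, c(qcol, "prs_tertile"), "analysis cohort")
  covs <- covariate_terms(covariates, index, drop = "prs_tertile")
  dat <- dplyr::filter(data, !is.na(.data$prs_tertile),
                       .data$prs_tertile != "unknown")
  dat$..q <- factor(dat[[qcol]])
  dat$..g <- droplevels(factor(dat$prs_tertile))

  base <- fit_coxph(cox_formula(c("..q", "..g"), covs), dat)
  full <- fit_coxph(cox_formula(c("..q", "..g", "..q:..g"), covs), dat)
  lrt <- stats::anova(base, full)
  p_mult <- lrt[["Pr(>|Chi|)"]][2] %||% lrt[["P(>|Chi|)"]][2]

  # 2x2 RERI view: extreme diet quintiles x extreme PRS tertiles
  d2 <- dat |>
    filter(.data[[qcol]] %in% c(1, 5), .data$..g %in% c("low", "high")) |>
    mutate(
      dh = .data[[qcol]] == 5,
      gh = .data$..g == "high",
      e10 = .data$dh & !.data$gh,
      e01 = !.data$dh & .data$gh,
      e11 = .data$dh & .data$gh
    )
  fit2 <- fit_coxph(cox_formula(c("e10", "e01", "e11"), covs), d2)
  keep <- c("e10TRUE", "e01TRUE", "e11TRUE")
  b <- coef(fit2)[keep]
  V <- vcov(fit2)[keep, keep]
  hr10 <- exp(b[[1]]); hr01 <- exp(b[[2]]); hr11 <- exp(b[[3]])
  reri <- hr11 - hr10 - hr01 + 1
  grad <- c(-hr10, -hr01, hr11)
  se <- sqrt(as.numeric(t(grad) %*% V %*% grad))
  z <- qnorm(0.975)

  by_prs <- NULL
  if (strata_fits) {
    by_prs <- purrr::map(setNames(levels(dat$..g), levels(dat$..g)), function(g) {
      fit_cox(dplyr::filter(dat, .data$..g == g),
              model_spec(index, "quintile", covariates,
                         drop_covariates = "prs_tertile"))
    })
  }
  structure(
    list(
      index = index, p_multiplicative = unname(p_mult),
      reri = tibble(estimate = reri, lo = reri - z * se, hi = reri + z * se,
                    se = se),
      joint_hrs = tibble(cell = c("diet_high_only", "prs_high_only", "both"),
                         hr = c(hr10, hr01, hr11)),
      by_prs = by_prs
    ),
    class = "interaction_result"
  )
}

#' @export
print.interaction_result <- function(x, ...) {
  cat("<interaction_result> ", x$index,
      ": multiplicative LRT p = ", format(signif(x$p_multiplicative, 3)),
      "; RERI = ", signif(x$reri$estimate, 3),
      " (", signif(x$reri$lo, 3), ", ", signif(x$reri$hi, 3), ")\n", sep = "")
  invisible(x)
}

#' Tidy an interaction result
#' @param x An `interaction_result`.
#' @param ... Unused.
#' @method tidy interaction_result
#' @export
tidy.interaction_result <- function(x, ...) {
  tibble(index = x$index, p_multiplicative = x$p_multiplicative,
         reri = x$reri$estimate, reri_lo = x$reri$lo, reri_hi = x$reri$hi)
}

#' Relative excess risk due to interaction from three hazard ratios
#'
#' `RERI = hr11 - hr10 - hr01 + 1`; zero under additivity of excess risks.
#'
#' @param hr10,hr01,hr11 Hazard ratios vs the doubly unexposed cell.
#' @return Numeric.
#' @export
reri <- function(hr10, hr01, hr11) hr11 - hr10 - hr01 + 1

#' Joint 15-group diet-by-genetics classification
#'
#' Crosses dietary score quintiles with PRS tertiles into 15 dummy-coded
#' cells; the highest-risk combination (lowest dietary score, low PRS) is
#' the reference.
#'
#' @param data Analysis cohort tibble.
#' @param index Score column name.
#' @param covariates Covariate set id.
#' @return An `hr_set` over the 15 cells (level labels `Q<q>:<tertile>`).
#' @export
joint_groups <- function(data, index, covariates = "model2") {
  qcol <- paste0(index, "_q")
  stop_missing_fields(data, c(qcol, "prs_tertile"), "analysis cohort")
  dat <- dplyr::filter(data, !is.na(.data$prs_tertile),
                       .data$prs_tertile != "unknown")
  tert <- c("low", "intermediate", "high")
  cells <- paste0("Q", rep(1:5, each = 3), ":", rep(tert, 5))
  dat$..cell <- factor(paste0("Q", dat[[qcol]], ":", dat$prs_tertile),
                       levels = cells)
  ev <- dat |>
    group_by(.data$..cell, .drop = FALSE) |>
    summarise(n = dplyr::n(), n_events = sum(.data$event),
              person_years = sum(.data$time_years), .groups = "drop")
  if (any(ev$n_events == 0)) {
    abort(paste0("Zero events in joint cell(s) ",
                 paste(ev$..cell[ev$n_events == 0], collapse = ", "),
                 "; enlarge the cohort or coarsen the grouping."))
  }
  covs <- covariate_terms(covariates, index, drop = "prs_tertile")
  fit <- fit_coxph(cox_formula("..cell", covs), dat)
  rows <- hr_row(fit, "^\\.\\.cell")
  structure(
    list(index = index, exposure = "joint_15",
         levels = tibble(
           level = cells,
           hr = c(1, rows$hr), lo = c(1, rows$lo), hi = c(1, rows$hi),
           log_hr = c(0, rows$log_hr), se = c(0, rows$se)
         ) |> bind_cols(dplyr::select(ev, "n", "n_events", "person_years")),
         per_sd = NULL, p_trend = NULL, fit = fit, covariates = covariates),
    class = "hr_set"
  )
}

#' Stratified association analyses with interaction tests
#'
#' Fits the per-SD score association within each level of a potential risk
#' modifier (the modifier itself is removed from the covariate set) and
#' tests effect modification by a likelihood-ratio test on the pooled model
#' with score x modifier product terms.
#'
#' @param data Analysis cohort tibble.
#' @param index Score column name.
#' @param modifier Column name of the stratifying variable.
#' @param covariates Covariate set id.
#' @return List with `strata` (tibble: stratum, per-SD HR/CI, events) and
#'   `p_interaction`.
#' @export
stratified_analysis <- function(data, index, modifier, covariates = "model2") {
  stop_missing_fields(data, c(index, modifier), "analysis cohort")
  drop <- c(modifier, if (modifier == "deprivation_q") "factor(deprivation_q)",
            if (modifier == "centre") "factor(centre)")
  covs <- covariate_terms(covariates, index, drop = drop)
  levels_ <- sort(unique(data[[modifier]]))
  if (length(levels_) < 1) abort("Empty modifier.")
  strata <- purrr::map_dfr(levels_, function(lv) {
    sub <- dplyr::filter(data, .data[[modifier]] == lv)
    if (nrow(sub) == 0 || sum(sub$event) == 0) {
      abort(paste0("Stratum '", lv, "' has no data or no events."))
    }
    sub$..x <- (sub[[index]] - mean(sub[[index]])) / sd(sub[[index]])
    fit <- fit_coxph(cox_formula("..x", covs), sub)
    hr_row(fit, "^\\.\\.x") |>
      mutate(stratum = as.character(lv), n = nrow(sub),
             n_events = sum(sub$event), .before = 1) |>
      dplyr::select(-"term")
  })
  p_int <- NA_real_
  if (length(levels_) > 1) {
    pooled <- data
    pooled$..x <- (pooled[[index]] - mean(pooled[[index]])) / sd(pooled[[index]])
    pooled$..m <- factor(pooled[[modifier]])
    base <- fit_coxph(cox_formula(c("..x", "..m"), covs), pooled)
    full <- fit_coxph(cox_formula(c("..x", "..m", "..x:..m"), covs), pooled)
    lrt <- stats::anova(base, full)
    p_int <- unname(lrt[["Pr(>|Chi|)"]][2] %||% lrt[["P(>|Chi|)"]][2])
  }
  list(strata = strata, p_interaction = p_int,
       modifier = modifier, index = index)
}
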
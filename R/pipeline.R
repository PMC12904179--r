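#' Pipeline configuration
#'
#' @param n_participants Synthetic cohort size.
#' @param seed Root seed, fanned out to per-stage streams.
#' @param indices Dietary indices to analyse.
#' @param covariates Covariate set for the main fits.
#' @param start_ages Life-table start ages.
#' @param n_draws Monte Carlo draws for the life-table CIs.
#' @param out_dir Output directory (`NULL` keeps everything in memory).
#' @param sim_params Optional full [simulation_params()] override.
#' @return `pipeline_config` list.
#' @export
pipeline_config <- function(n_participants = 5000, seed = 1L,
                            indices = c("ahei", "amed", "hpdi", "dash", "drrd"),
                            covariates = "model2",
                            start_ages = c(45, 50, 55, 60),
                            n_draws = 500,
                            out_dir = NULL,
                            sim_params = NULL) {
  known <- c("ahei", "amed", "hpdi", "dash", "drrd")
  bad <- setdiff(indices, known)
  if (length(bad)) {
    abort(paste0("Unknown index name(s): ", paste(bad, collapse = ", "),
                 "; expected among ", paste(known, collapse = ", "), "."))
  }
  structure(
    list(n_participants = n_participants, seed = seed, indices = indices,
         covariates = covariates, start_ages = start_ages, n_draws = n_draws,
         out_dir = out_dir, sim_params = sim_params),
    class = "pipeline_config"
  )
}

write_stage <- function(tbl, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  path <- file.path(out_dir, paste0(name, ".csv"))
  utils::write.csv(tbl, path, row.names = FALSE)
  invisible(path)
}

#' Run the full simulate-prepare-score-fit-lifetable pipeline
#'
#' Stages, in fixed order: synthetic cohort generation; exclusions and
#' assessment averaging; dietary scoring and polygenic score; quintile Cox
#' fits (with trend and per-SD) per index; sex-specific quintile fits feeding
#' the life-table engine; life expectancy and years gained at the configured
#' start ages. Outputs a baseline-characteristics table, HR tables, a
#' life-expectancy table, the exclusion report, and a manifest recording the
#' config and seed. Deterministic given the config.
#'
#' @param config A [pipeline_config()].
#' @return List with `cohort`, `analysis`, `baseline`, `hr_tables`,
#'   `le_estimates`, `report`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  params <- config$sim_params %||%
    simulation_params(n_participants = config$n_participants, seed = config$seed)
  cohort <- generate_cohort(params)
  built <- build_analysis_cohort(cohort)
  dat <- built$data

  baseline <- summarize_baseline(dat, index = config$indices[1])
  write_stage(baseline, out_dir, "baseline_characteristics")
  write_stage(tidy(built$report), out_dir, "exclusion_report")

  hr_tables <- purrr::map(
    setNames(config$indices, config$indices),
    function(idx) fit_cox(dat, model_spec(idx, "quintile", config$covariates))
  )
  write_stage(purrr::map_dfr(hr_tables, tidy), out_dir, "hazard_ratios")

  # life-table stage: sex-specific quintile HRs for the first index
  idx <- config$indices[1]
  qcol <- paste0(idx, "_q")
  sex_hrs <- purrr::map_dfr(c("male", "female"), function(s) {
    sub <- dplyr::filter(dat, .data$sex == s)
    hs <- fit_cox(sub, model_spec(idx, "quintile", config$covariates,
                                  drop_covariates = "sex"))
    hs$levels |>
      dplyr::transmute(sex = s, group = .data$level, hr = .data$hr,
                       lo = .data$lo, hi = .data$hi)
  })
  dat$quintile_group <- paste0("Q", dat[[qcol]])
  prev <- prevalence_from_cohort(dat, "quintile_group")
  lt <- generate_population_life_table()
  le <- run_life_expectancy(sex_hrs, lt, prev, reference = "Q1",
                            start_ages = config$start_ages,
                            n_draws = config$n_draws, seed = config$seed)
  write_stage(le, out_dir, "life_expectancy")

  manifest <- list(
    config = config[setdiff(names(config), "sim_params")],
    seed = config$seed,
    n_input = built$report$n_input,
    n_analysed = nrow(dat),
    n_events = sum(dat$event),
    person_years = sum(dat$time_years),
    package_version = as.character(utils::packageVersion("dietspan"))
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(cohort = cohort, analysis = dat, baseline = baseline,
       hr_tables = hr_tables, le_estimates = le, report = built$report,
       manifest = manifest)
}

#' Baseline characteristics by quintile of a dietary score
#'
#' Continuous variables as mean (SD), counts as n (%), for the overall
#' cohort and the extreme quintiles of the chosen index.
#'
#' @param data Analysis cohort tibble.
#' @param index Score column whose quintiles define the strata.
#' @param continuous,categorical Variable names to summarise.
#' @return Long tibble: `variable`, `level`, `statistic`, one column per
#'   stratum (`overall`, `Q1`, `Q5`).
#' @export
summarize_baseline <- function(data, index = "ahei",
                               continuous = c("age", "energy_kcal", "alcohol_g", "prs"),
                               categorical = c("sex", "smoking", "activity",
                                               "bmi_class", "education")) {
  qcol <- paste0(index, "_q")
  stop_missing_fields(data, qcol, "analysis cohort")
  strata <- list(
    overall = data,
    Q1 = dplyr::filter(data, .data[[qcol]] == 1),
    Q5 = dplyr::filter(data, .data[[qcol]] == 5)
  )
  one_stratum <- function(d) {
    cont <- purrr::map_dfr(intersect(continuous, names(d)), function(v) {
      tibble(variable = v, level = NA_character_,
             statistic = "mean_sd",
             value = sprintf("%.1f (%.1f)", mean(d[[v]], na.rm = TRUE),
                             sd(d[[v]], na.rm = TRUE)))
    })
    cat_ <- purrr::map_dfr(intersect(categorical, names(d)), function(v) {
      tab <- table(d[[v]])
      tibble(variable = v, level = names(tab), statistic = "n_pct",
             value = sprintf("%d (%.1f%%)", as.integer(tab),
                             100 * as.integer(tab) / nrow(d)))
    })
    bind_rows(cont, cat_)
  }
  out <- purrr::imap(strata, function(d, nm) {
    one_stratum(d) |> rename(!!nm := "value")
  })
  purrr::reduce(out, left_join, by = c("variable", "level", "statistic"))
}
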
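#' Exclusion rule configuration
#'
#' Defaults mirror the study design: at least two completed dietary
#' assessments, sex-specific plausible mean energy intake (800-4200 kcal/day
#' in men, 600-3500 kcal/day in women), and no prevalent cardiovascular
#' disease or cancer at the last assessment. `energy_screen = "mean"` applies
#' the bounds to the assessment-averaged energy (the analysed exposure);
#' `"per_day"` flags any single implausible assessment day.
#' `genetic_subset = TRUE` additionally requires genotype data and European
#' ancestry.
#'
#' @param min_assessments Minimum completed dietary assessments.
#' @param energy_bounds Named list of per-sex `c(lower, upper)` kcal/day.
#' @param energy_screen `"mean"` or `"per_day"`.
#' @param exclude_prevalent Drop prevalent CVD/cancer.
#' @param genetic_subset Restrict to genotyped European-ancestry participants.
#' @return List of class `exclusion_rules`.
#' @export
exclusion_rules <- function(min_assessments = 2L,
                            energy_bounds = list(male = c(800, 4200),
                                                 female = c(600, 3500)),
                            energy_screen = c("mean", "per_day"),
                            exclude_prevalent = TRUE,
                            genetic_subset = FALSE) {
  structure(
    list(min_assessments = min_assessments, energy_bounds = energy_bounds,
         energy_screen = match.arg(energy_screen),
         exclude_prevalent = exclude_prevalent,
         genetic_subset = genetic_subset),
    class = "exclusion_rules"
  )
}

#' Apply the study inclusion and exclusion rules
#'
#' Rules are applied in a fixed documented order — (1) fewer than the
#' required assessments, (2) implausible energy, (3) prevalent CVD/cancer,
#' (4) genetic-subset requirements — with sequential counts, so per-rule
#' counts depend on order but the retained set does not (the rules are
#' conjunctive). Participants with missing sex cannot be screened against
#' sex-specific energy bounds and are routed to an explicit `unclassifiable`
#' bucket, never silently kept.
#'
#' @param cohort A `synthetic_cohort`, or a list with `intakes`,
#'   `participants` (and `genotypes` when `genetic_subset`).
#' @param rules An [exclusion_rules()] object.
#' @return List with `participants` (retained rows), `intakes` (their
#'   assessment rows), and `report` (an `exclusion_report` tibble: one row
#'   per rule with `n_removed`, plus retained/unclassifiable counts).
#' @export
apply_exclusions <- function(cohort, rules = exclusion_rules()) {
  stopifnot(inherits(rules, "exclusion_rules"))
  participants <- cohort$participants
  intakes <- cohort$intakes
  stop_missing_fields(participants, c("participant_id", "sex"), "participants")
  stop_missing_fields(intakes, c("participant_id", "energy_kcal"), "intakes")
  n_input <- nrow(participants)

  unclassifiable <- participants$participant_id[
    is.na(participants$sex) | !participants$sex %in% c("male", "female")
  ]
  pool <- dplyr::filter(participants, !.data$participant_id %in% unclassifiable)
  steps <- tibble(rule = character(), n_removed = integer())
  drop_step <- function(pool, rule, drop_ids) {
    steps <<- bind_rows(steps, tibble(rule = rule,
                                      n_removed = sum(pool$participant_id %in% drop_ids)))
    dplyr::filter(pool, !.data$participant_id %in% drop_ids)
  }

  n_assess <- intakes |> count(.data$participant_id, name = "n_assessments")
  under <- pool |>
    left_join(n_assess, by = "participant_id") |>
    mutate(n_assessments = dplyr::coalesce(.data$n_assessments, 0L)) |>
    filter(.data$n_assessments < rules$min_assessments) |>
    pull("participant_id")
  pool <- drop_step(pool, "under_assessed", under)

  energy <- intakes |>
    group_by(.data$participant_id) |>
    summarise(mean_energy = mean(.data$energy_kcal, na.rm = TRUE),
              min_energy = min(.data$energy_kcal, na.rm = TRUE),
              max_energy = max(.data$energy_kcal, na.rm = TRUE), .groups = "drop")
  screened <- pool |> left_join(energy, by = "participant_id")
  bad_energy <- purrr::map_lgl(seq_len(nrow(screened)), function(i) {
    b <- rules$energy_bounds[[screened$sex[i]]]
    if (rules$energy_screen == "mean") {
      screened$mean_energy[i] < b[1] || screened$mean_energy[i] > b[2]
    } else {
      screened$min_energy[i] < b[1] || screened$max_energy[i] > b[2]
    }
  })
  pool <- drop_step(pool, "implausible_energy", screened$participant_id[bad_energy])

  if (rules$exclude_prevalent) {
    stop_missing_fields(pool, c("prevalent_cvd", "prevalent_cancer"), "participants")
    prev <- pool |>
      filter(.data$prevalent_cvd | .data$prevalent_cancer) |>
      pull("participant_id")
    pool <- drop_step(pool, "prevalent_cvd_cancer", prev)
  }

  if (rules$genetic_subset) {
    genotyped <- cohort$genotypes$participant_id
    no_gen <- pool |>
      filter(!.data$participant_id %in% genotyped |
               !dplyr::coalesce(.data$european_ancestry, FALSE)) |>
      pull("participant_id")
    pool <- drop_step(pool, "missing_genotype_or_ancestry", no_gen)
  }

  report <- structure(
    list(steps = steps, n_input = n_input,
         n_unclassifiable = length(unclassifiable),
         n_retained = nrow(pool)),
    class = "exclusion_report"
  )
  list(
    participants = pool,
    intakes = dplyr::filter(intakes, .data$participant_id %in% pool$participant_id),
    report = report
  )
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("<exclusion_report> input:", x$n_input,
      "| unclassifiable:", x$n_unclassifiable,
      "| retained:", x$n_retained, "\n")
  print(x$steps)
  invisible(x)
}

#' Tidy an exclusion report into one row per rule
#' @param x An `exclusion_report`.
#' @param ... Unused.
#' @method tidy exclusion_report
#' @export
tidy.exclusion_report <- function(x, ...) {
  bind_rows(
    tibble(rule = "unclassifiable_sex", n_removed = x$n_unclassifiable),
    x$steps,
    tibble(rule = "retained", n_removed = NA_integer_)
  ) |>
    mutate(n_retained_after = x$n_input - cumsum(dplyr::coalesce(.data$n_removed, 0L)))
}

#' Average repeated dietary assessments into one intake profile
#'
#' Arithmetic mean per field across a participant's assessments. Food-group
#' fields treat a missing value as zero consumption (24-hour-recall
#' semantics); nutrient totals are averaged over non-missing days only. Rows
#' with any imputed or skipped value are flagged.
#'
#' @param intakes Assessment-level tibble (`participant_id`, `assessment`,
#'   intake fields).
#' @param min_assessments Participants with fewer assessments trigger an
#'   error — they should have been excluded upstream.
#' @return One-row-per-participant tibble of averaged fields plus
#'   `n_assessments` and `had_missing`.
#' @export
average_assessments <- function(intakes, min_assessments = 2L) {
  dict <- intake_fields()
  fields <- intersect(dict$field, names(intakes))
  if (!length(fields)) abort("No recognised intake fields to average.")
  counts <- intakes |> count(.data$participant_id, name = "n_assessments")
  if (any(counts$n_assessments < min_assessments)) {
    abort(paste0(
      sum(counts$n_assessments < min_assessments),
      " participant(s) have fewer than ", min_assessments,
      " assessments; apply exclusions before averaging."
    ))
  }
  zero_fields <- intersect(fields, dict$field[dict$missing_as_zero])
  filled <- intakes |>
    mutate(across(dplyr::all_of(zero_fields), ~ dplyr::coalesce(.x, 0)))
  had_missing <- intakes |>
    group_by(.data$participant_id) |>
    summarise(had_missing = anyNA(dplyr::pick(dplyr::all_of(fields))),
              .groups = "drop")
  filled |>
    group_by(.data$participant_id) |>
    summarise(across(dplyr::all_of(fields), ~ mean(.x, na.rm = TRUE)),
              n_assessments = dplyr::n(), .groups = "drop") |>
    left_join(had_missing, by = "participant_id")
}

#' Follow-up person-years and event flag from dates
#'
#' Follow-up runs from the most recent dietary assessment to death, loss to
#' follow-up, or the administrative censoring date, whichever comes first;
#' years use the 365.25-day convention. The event flag is true only when
#' death is the earliest end point.
#'
#' @param baseline_date,death_date,loss_date `Date` vectors (death/loss may
#'   be `NA`).
#' @param admin_end Administrative censoring date.
#' @return Tibble with `follow_up_years` and `event`.
#' @export
person_years <- function(baseline_date, death_date = NULL, loss_date = NULL,
                         admin_end = as.Date("2022-11-30")) {
  n <- length(baseline_date)
  death_date <- death_date %||% as.Date(rep(NA, n))
  loss_date <- loss_date %||% as.Date(rep(NA, n))
  if (any(!is.na(death_date) & death_date < baseline_date)) {
    abort("Death date precedes baseline: corrupted input.")
  }
  end <- pmin(death_date, loss_date, as.Date(rep(admin_end, n)), na.rm = TRUE)
  event <- !is.na(death_date) & death_date == end
  yrs <- as.numeric(end - baseline_date) / 365.25
  if (any(yrs < 0)) abort("Negative follow-up: an end date precedes baseline.")
  tibble(follow_up_years = yrs, event = event)
}

#' Classify an ICD-10 underlying-cause code into the analysis cause classes
#'
#' I00-I99 cardiovascular, C00-C97 cancer, G00-G99 neurodegenerative,
#' J00-J99 respiratory, anything else `other`.
#'
#' @param icd10_code Character vector of ICD-10 codes (e.g. `"I21.9"`).
#' @return Character vector of cause classes.
#' @export
classify_cause <- function(icd10_code) {
  ok <- stringr::str_detect(icd10_code, "^[A-Z][0-9]{2}")
  if (any(!ok)) {
    abort(paste0("Malformed ICD-10 code(s): ",
                 paste(unique(icd10_code[!ok]), collapse = ", ")))
  }
  letter <- stringr::str_sub(icd10_code, 1, 1)
  num <- as.integer(stringr::str_sub(icd10_code, 2, 3))
  dplyr::case_when(
    letter == "I" ~ "cvd",
    letter == "C" & num <= 97 ~ "cancer",
    letter == "G" ~ "neurodegenerative",
    letter == "J" ~ "respiratory",
    TRUE ~ "other"
  )
}

#' Alcohol covariate categories
#'
#' Default edges follow the fully adjusted models' seven categories
#' (0, 0.1-5, 5.1-10, 10.1-15, 15.1-20, 20.1-30, >30 g/day); pass different
#' `edges` to use the coarser five-category scheme.
#'
#' @param alcohol_g Grams/day.
#' @param edges Interior upper edges (g/day) of the non-zero categories.
#' @return Factor with a level per category.
#' @export
alcohol_category <- function(alcohol_g, edges = c(5, 10, 15, 20, 30)) {
  labs <- c("0",
            paste0(c(0.1, edges[-length(edges)] + 0.1), "-", edges),
            paste0(">", edges[length(edges)]))
  cut(alcohol_g, breaks = c(-Inf, 0, edges, Inf), labels = labs, right = TRUE)
}

#' Assemble the model-ready analysis cohort
#'
#' Runs exclusions, averages assessments, computes the five dietary scores
#' and quintiles, the polygenic score and tertiles, and codes covariates —
#' returning one row per retained participant with everything the Cox models
#' need.
#'
#' @param cohort A `synthetic_cohort` (or equivalent list).
#' @param rules [exclusion_rules()].
#' @param specs Scoring specifications ([default_scoring_specs()]).
#' @return List with `data` (the analysis tibble), `profiles` (averaged
#'   intakes), and `report` (exclusions).
#' @export
build_analysis_cohort <- function(cohort, rules = exclusion_rules(),
                                  specs = default_scoring_specs()) {
  kept <- apply_exclusions(cohort, rules)
  profiles <- average_assessments(kept$intakes, rules$min_assessments) |>
    left_join(dplyr::select(kept$participants, "participant_id", "sex"),
              by = "participant_id")
  scores <- score_diet(profiles, specs)
  prs <- compute_prs(cohort$genotypes, cohort$snp_weights)
  data <- kept$participants |>
    left_join(scores, by = "participant_id") |>
    left_join(dplyr::select(profiles, "participant_id", "energy_kcal", "alcohol_g"),
              by = "participant_id") |>
    left_join(dplyr::select(prs, "participant_id", "prs", "prs_tertile"),
              by = "participant_id") |>
    mutate(
      # ungenotyped participants keep an explicit level, never dropped silently
      prs_tertile = factor(
        dplyr::coalesce(as.character(.data$prs_tertile), "unknown"),
        levels = c("low", "intermediate", "high", "unknown")
      ),
      alcohol_cat = alcohol_category(.data$alcohol_g)
    )
  list(data = data, profiles = profiles, report = kept$report)
}
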
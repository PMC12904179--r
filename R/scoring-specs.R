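#' Declarative dietary index scoring specification
#'
#' A `scoring_spec` describes one dietary index as a component table: which
#' intake fields feed each component (multiple fields are summed), whether
#' higher intake is better, worse, or intermediate-best, the scoring rule
#' (absolute anchors, cohort quintile rank, or a tent function), whether
#' ranking is sex-specific, and the point range. The constructor proves that
#' the component point extremes sum to the declared index range, so range
#' closure is a structural property rather than a runtime accident.
#'
#' @param index Index name (e.g. `"ahei"`).
#' @param components Tibble with columns `component`, `fields` (list of
#'   character vectors), `direction` (`"higher"`, `"lower"`, `"intermediate"`),
#'   `rule` (`"absolute"`, `"quintile"`, `"tent"`), `sex_specific` (logical),
#'   `min_points`, `max_points`, `anchors` (list; see Details).
#' @param range Length-2 numeric, the declared index range.
#'
#' @details Anchors: for `rule = "absolute"` a list with `worst` and `best`
#' values (each either a scalar or a named list with `male`/`female` entries);
#' for `rule = "tent"` a list with `zero_pts`, `opt_lo`, `opt_hi`, `upper`
#' (scalar or per-sex); quintile components need no anchors.
#'
#' @return An object of class `scoring_spec`.
#' @export
scoring_spec <- function(index, components, range) {
  stopifnot(is.character(index), length(range) == 2)
  needed <- c("component", "fields", "direction", "rule", "sex_specific",
              "min_points", "max_points", "anchors")
  stop_missing_fields(components, needed, paste0("scoring_spec(", index, ")"))
  if (anyDuplicated(components$component)) {
    abort("Duplicate component names in scoring spec.")
  }
  bad_dir <- setdiff(components$direction, c("higher", "lower", "intermediate"))
  if (length(bad_dir)) abort(paste0("Unknown direction: ", bad_dir[1]))
  bad_rule <- setdiff(components$rule, c("absolute", "quintile", "tent"))
  if (length(bad_rule)) abort(paste0("Unknown rule: ", bad_rule[1]))
  known <- intake_fields()$field
  bad_fields <- setdiff(unlist(components$fields), known)
  if (length(bad_fields)) {
    abort(paste0("Component field(s) not in the intake dictionary: ",
                 paste(bad_fields, collapse = ", ")))
  }
  if (!isTRUE(all.equal(sum(components$min_points), range[1])) ||
      !isTRUE(all.equal(sum(components$max_points), range[2]))) {
    abort(paste0(
      "Component point extremes (", sum(components$min_points), "-",
      sum(components$max_points), ") do not close the declared range (",
      range[1], "-", range[2], ")."
    ))
  }
  structure(
    list(index = index, components = components, range = range),
    class = "scoring_spec"
  )
}

#' @export
print.scoring_spec <- function(x, ...) {
  cat("<scoring_spec> ", x$index, ": ", nrow(x$components),
      " components, range ", x$range[1], "-", x$range[2], "\n", sep = "")
  print(dplyr::select(x$components, "component", "direction", "rule",
                      "sex_specific", "min_points", "max_points"))
  invisible(x)
}

abs_comp <- function(component, fields, worst, best, max_points = 10) {
  tibble(
    component = component, fields = list(fields),
    direction = if (is.numeric(worst) && is.numeric(best) && worst > best) "lower" else "higher",
    rule = "absolute",
    sex_specific = is.list(worst) || is.list(best),
    min_points = 0, max_points = max_points,
    anchors = list(list(worst = worst, best = best))
  )
}

quint_comp <- function(component, fields, direction = "higher", sex_specific = FALSE) {
  tibble(
    component = component, fields = list(fields), direction = direction,
    rule = "quintile", sex_specific = sex_specific,
    min_points = 1, max_points = 5, anchors = list(NULL)
  )
}

#' Shipped default scoring specifications
#'
#' Defaults encode the canonical published definitions of the five indices:
#' AHEI-2010 (11 components, absolute anchors with linear interpolation,
#' 0-110), AMED (10 food groups, sex-specific cohort quintiles, 10-50), hPDI
#' (17 components, cohort quintiles with reverse scoring of less-healthy plant
#' and animal foods, 17-85), DASH (8 food groups, cohort quintiles, 8-40), and
#' DRRD (9 components including dietary fiber and glycemic index, cohort
#' quintiles, 9-45). Anchor values are package defaults, fully overridable by
#' supplying a modified `scoring_spec`; AHEI sodium is scored against absolute
#' anchors here rather than cohort deciles.
#'
#' @param index Optionally a single index name; otherwise all five are
#'   returned as a named list.
#' @return A `scoring_spec` or a named list of them.
#' @export
default_scoring_specs <- function(index = NULL) {
  ahei <- scoring_spec("ahei", dplyr::bind_rows(
    abs_comp("vegetables",   "vegetables",  worst = 0,   best = 5),
    abs_comp("fruits",       "fruits",      worst = 0,   best = 4),
    abs_comp("whole_grains", "whole_grains",
             worst = list(male = 0, female = 0),
             best  = list(male = 90, female = 75)),
    abs_comp("ssb_juice",    c("ssb", "fruit_juice"), worst = 1,   best = 0),
    abs_comp("nuts_legumes", c("nuts", "legumes"),    worst = 0,   best = 1),
    abs_comp("red_processed_meat", c("red_meat", "processed_meat"),
             worst = 1.5, best = 0),
    abs_comp("trans_fat",    "trans_fat_pct", worst = 4,    best = 0.5),
    abs_comp("n3_fat",       "n3_mg",         worst = 0,    best = 250),
    abs_comp("pufa",         "pufa_pct",      worst = 2,    best = 10),
    abs_comp("sodium",       "sodium_mg",     worst = 3400, best = 1100),
    tibble(
      component = "alcohol", fields = list("alcohol_g"),
      direction = "intermediate", rule = "tent", sex_specific = TRUE,
      min_points = 0, max_points = 10,
      anchors = list(list(
        zero_pts = 2.5,
        opt_lo = 7, opt_hi = list(male = 28, female = 21),
        upper = list(male = 49, female = 35)
      ))
    )
  ), range = c(0, 110))

  amed <- scoring_spec("amed", dplyr::bind_rows(
    quint_comp("vegetables",     "vegetables",     sex_specific = TRUE),
    quint_comp("fruits",         "fruits",         sex_specific = TRUE),
    quint_comp("legumes",        "legumes",        sex_specific = TRUE),
    quint_comp("nuts",           "nuts",           sex_specific = TRUE),
    quint_comp("whole_grains",   "whole_grains",   sex_specific = TRUE),
    quint_comp("fish",           "fish",           sex_specific = TRUE),
    quint_comp("mufa_sfa",       "mufa_sfa_ratio", sex_specific = TRUE),
    quint_comp("alcohol",        "alcohol_g",      sex_specific = TRUE),
    quint_comp("red_meat",       "red_meat",       direction = "lower", sex_specific = TRUE),
    quint_comp("processed_meat", "processed_meat", direction = "lower", sex_specific = TRUE)
  ), range = c(10, 50))

  hpdi <- scoring_spec("hpdi", dplyr::bind_rows(
    # healthy plant foods, scored positively
    quint_comp("whole_grains", "whole_grains"),
    quint_comp("fruits",       "fruits"),
    quint_comp("vegetables",   "vegetables"),
    quint_comp("nuts",         "nuts"),
    quint_comp("legumes",      "legumes"),
    quint_comp("veg_oils",     "veg_oils"),
    quint_comp("tea_coffee",   "tea_coffee"),
    # less-healthy plant foods, reverse scored
    quint_comp("fruit_juice",     "fruit_juice",     direction = "lower"),
    quint_comp("refined_grains",  "refined_grains",  direction = "lower"),
    quint_comp("potatoes",        "potatoes",        direction = "lower"),
    quint_comp("ssb",             "ssb",             direction = "lower"),
    quint_comp("sweets_desserts", "sweets_desserts", direction = "lower"),
    # animal foods, reverse scored
    quint_comp("animal_fat", "animal_fat", direction = "lower"),
    quint_comp("dairy", c("whole_fat_dairy", "low_fat_dairy"), direction = "lower"),
    quint_comp("eggs",       "eggs",       direction = "lower"),
    quint_comp("fish_seafood", "fish",     direction = "lower"),
    quint_comp("meat", c("red_meat", "processed_meat", "poultry"), direction = "lower")
  ), range = c(17, 85))

  dash <- scoring_spec("dash", dplyr::bind_rows(
    quint_comp("whole_grains",  "whole_grains"),
    quint_comp("fruits",        "fruits"),
    quint_comp("vegetables",    "vegetables"),
    quint_comp("nuts_legumes",  c("nuts", "legumes")),
    quint_comp("low_fat_dairy", "low_fat_dairy"),
    quint_comp("sodium",        "sodium_mg",  direction = "lower"),
    quint_comp("red_processed_meat", c("red_meat", "processed_meat"), direction = "lower"),
    quint_comp("ssb",           "ssb",        direction = "lower")
  ), range = c(8, 40))

  drrd <- scoring_spec("drrd", dplyr::bind_rows(
    quint_comp("cereal_fiber", "fiber_g"),
    quint_comp("coffee",       "tea_coffee"),
    quint_comp("nuts",         "nuts"),
    quint_comp("whole_fruits", "fruits"),
    quint_comp("pufa_sfa",     "pufa_sfa_ratio"),
    quint_comp("glycemic_index", "glycemic_index", direction = "lower"),
    quint_comp("ssb_juice", c("ssb", "fruit_juice"), direction = "lower"),
    quint_comp("red_processed_meat", c("red_meat", "processed_meat"), direction = "lower"),
    quint_comp("trans_fat", "trans_fat_pct", direction = "lower")
  ), range = c(9, 45))

  specs <- list(ahei = ahei, amed = amed, hpdi = hpdi, dash = dash, drrd = drrd)
  if (is.null(index)) return(specs)
  if (!index %in% names(specs)) {
    abort(paste0("Unknown index '", index, "'; expected one of ",
                 paste(names(specs), collapse = ", "), "."))
  }
  specs[[index]]
}

#' Drop the alcohol component from an index specification
#'
#' Sensitivity-analysis variant: removes the alcohol component from AHEI or
#' AMED, shrinking the declared range accordingly (AHEI 0-100, AMED 9-45).
#'
#' @param spec A `scoring_spec` containing an `alcohol` component.
#' @return A `scoring_spec` without the alcohol component.
#' @export
spec_without_alcohol <- function(spec) {
  stopifnot(inherits(spec, "scoring_spec"))
  keep <- spec$components$component != "alcohol"
  if (all(keep)) abort(paste0("Index '", spec$index, "' has no alcohol component."))
  comp <- spec$components[keep, ]
  scoring_spec(paste0(spec$index, "_no_alcohol"), comp,
               range = c(sum(comp$min_points), sum(comp$max_points)))
}
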
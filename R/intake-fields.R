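#' Canonical intake field dictionary
#'
#' Every intake profile consumed by the scorers is a wide table with one row
#' per participant (or participant-assessment) and one column per field below.
#' Food groups are daily servings unless the unit says otherwise; nutrients
#' carry their conventional units. The dictionary also records whether missing
#' values are treated as zero consumption (food groups, 24-hour-recall
#' semantics) or as genuinely missing (nutrient totals, averaged over
#' non-missing assessment days).
#'
#' @return A tibble with columns `field`, `unit`, `kind` ("food" or
#'   "nutrient"), and `missing_as_zero`.
#' @export
intake_fields <- function() {
  food <- tibble::tribble(
    ~field,            ~unit,
    "vegetables",      "servings/day",
    "fruits",          "servings/day",
    "fruit_juice",     "servings/day",
    "whole_grains",    "g/day",
    "refined_grains",  "servings/day",
    "legumes",         "servings/day",
    "nuts",            "servings/day",
    "fish",            "servings/day",
    "poultry",         "servings/day",
    "red_meat",        "servings/day",
    "processed_meat",  "servings/day",
    "eggs",            "servings/day",
    "whole_fat_dairy", "servings/day",
    "low_fat_dairy",   "servings/day",
    "potatoes",        "servings/day",
    "ssb",             "servings/day",
    "sweets_desserts", "servings/day",
    "veg_oils",        "servings/day",
    "animal_fat",      "servings/day",
    "tea_coffee",      "cups/day"
  )
  nutrient <- tibble::tribble(
    ~field,            ~unit,
    "energy_kcal",     "kcal/day",
    "fiber_g",         "g/day",
    "sodium_mg",       "mg/day",
    "alcohol_g",       "g/day",
    "trans_fat_pct",   "% energy",
    "pufa_pct",        "% energy",
    "n3_mg",           "mg/day",
    "glycemic_index",  "dimensionless",
    "mufa_sfa_ratio",  "ratio",
    "pufa_sfa_ratio",  "ratio"
  )
  dplyr::bind_rows(
    dplyr::mutate(food, kind = "food", missing_as_zero = TRUE),
    dplyr::mutate(nutrient, kind = "nutrient", missing_as_zero = FALSE)
  )
}
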
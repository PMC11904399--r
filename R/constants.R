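#' Canonical nutrient slot names
#'
#' The derivation engine tracks 38 named daily (or weekly) quantities: energy
#' and the macronutrient fractions, minerals, vitamins, the three fish
#' fatty-acid slots and caffeine. Composition tables must resolve every slot
#' except \code{caffeine} and the fish fatty acids, which come from closed-form
#' estimators rather than the composition lookup.
#'
#' @return Character vector of slot names in canonical column order.
#' @export
nutrient_slots <- function() {
  c(
    "energy_kj", "protein_g", "fat_g", "satfat_g", "mufa_g", "pufa_g",
    "cholesterol_mg", "carbohydrate_g", "starch_g", "sugars_g", "nmes_g",
    "nsp_g", "calcium_mg", "potassium_mg", "sodium_mg", "phosphorus_mg",
    "magnesium_mg", "folate_ug", "iron_mg", "zinc_mg", "vitamin_c_mg",
    "thiamin_mg", "riboflavin_mg", "retinol_ug", "vitamin_e_mg",
    "vitamin_d_ug", "vitamin_b6_mg", "vitamin_b12_ug", "niacin_eq_mg",
    "niacin_mg", "tryptophan_mg", "carotene_ug", "selenium_ug", "iodine_ug",
    "n3_fish_g", "dha_fish_g", "epa_fish_g", "caffeine_mg"
  )
}

#' Nutrient slots resolved through the composition table
#'
#' @return Character vector: all slots except caffeine and the fish
#'   fatty-acid slots.
#' @export
composition_slots <- function() {
  setdiff(nutrient_slots(), c("n3_fish_g", "dha_fish_g", "epa_fish_g", "caffeine_mg"))
}

# Variant tags recognised in portion-table headers. Unknown tags are a load
# error, never silently ignored.
variant_tags <- function() {
  c("default", "vitaminE", "vitaminC", "folate", "retinol", "carotene",
    "zinc", "pyridoxine", "niacin", "fattyAcids", "totalFatEnergy",
    "fat_all", "fat_some", "fat_none")
}

# Which nutrient slots each nutrient-specific variant tag serves. A question's
# portion list for slot n is the variant whose tag covers n, else the default.
variant_slot_map <- function() {
  list(
    vitaminE       = "vitamin_e_mg",
    vitaminC       = "vitamin_c_mg",
    folate         = "folate_ug",
    retinol        = "retinol_ug",
    carotene       = "carotene_ug",
    zinc           = "zinc_mg",
    pyridoxine     = "vitamin_b6_mg",
    niacin         = "niacin_mg",
    fattyAcids     = c("satfat_g", "mufa_g", "pufa_g"),
    totalFatEnergy = c("fat_g", "energy_kj")
  )
}

#' Default derivation constants
#'
#' All printed constants of the derivation engine, plus the handful of
#' portion-size assumptions the source tables leave unstated, in one nested
#' list. Every value can be overridden through [ffq_config()] so the engine
#' never hard-codes a constant out of reach.
#'
#' Printed values: the five weekly frequency weights (0, 0.5, 2, 5.5, 10 with
#' missing treated as never), bread-slice category midpoints with missing
#' recoded to 1.5 slices/day, spread-slices missing recoded to 2 and capped at
#' 6, soft-drink frequency fixed at 2/week, per-portion fish n-3 of 0.32 g
#' (white), 0.89 g (oily) and 0.35 g (shellfish), and caffeine at 27 mg per
#' cup of tea, 57 mg per cup of coffee and 20 mg per cola drink.
#'
#' Non-printed defaults (documented as package choices): per-slice spreading
#' fat 7 g, sugar 5 g per spoon, milk-use volumes (tea/coffee 30 ml, cereal
#' and pudding 100 ml, drink and milky drink 200 ml), soft-drink portion
#' 110 g, EPA/DHA per-portion splits consistent with a DHA:n-3 ratio of about
#' 0.47 and EPA:n-3 of about 0.33 per fish class, Schofield female 18-29
#' basal metabolic rate coefficients and Goldberg-style plausibility bounds.
#'
#' @return Nested list of constants.
#' @export
default_constants <- function() {
  list(
    frequency_weights = list(
      "never or rarely"      = 0,
      "once in 2 weeks"      = 0.5,
      "1-3 times a week"     = 2,
      "4-7 times a week"     = 5.5,
      "more than once a day" = 10,
      missing                = 0
    ),
    bread = list(
      slices_by_category = list("less than 1" = 0.5, "1-2" = 1.5,
                                "3-4" = 3.5, "5 or more" = 5.5),
      missing_slices = 1.5
    ),
    spread = list(
      grams_per_slice = 7,
      missing_slices  = 2,
      max_slices      = 6
    ),
    sugar = list(
      grams_per_spoon = 5,
      food_code       = 8888
    ),
    milk = list(
      use_volumes_ml = list(tea = 30, coffee = 30, cereal = 100,
                            pudding = 100, drink = 200, milky_drink = 200),
      use_weights    = list("yes usually" = 1, "yes sometimes" = 0.5,
                            "no not at all" = 0, missing = 0)
    ),
    type_weights = list("yes usually" = 1, "yes sometimes" = 0.5,
                        "no not at all" = 0, yes = 1, no = 0, missing = 0),
    soft_drinks = list(
      frequency_per_week = 2,
      portion_g          = 110,
      sugary_fraction    = list("always" = 0, "sometimes" = 0.5,
                                "not at all" = 1,
                                "don't drink soft drinks" = 0, missing = 1)
    ),
    fish = list(
      n3_per_portion_g  = list(white = 0.32, oily = 0.89, shellfish = 0.35),
      epa_per_portion_g = list(white = 0.10, oily = 0.30, shellfish = 0.12),
      dha_per_portion_g = list(white = 0.16, oily = 0.42, shellfish = 0.16)
    ),
    caffeine = list(
      mg_per_cup_tea    = 27,
      mg_per_cup_coffee = 57,
      mg_per_cola       = 20
    ),
    energy_conversion_kj_per_g = list(protein = 17, fat = 37, carbohydrate = 16),
    aoac_factor = 1.33,
    misreporting = list(
      schofield = list(weight_coef_mj = 0.062, intercept_mj = 2.036),
      pal = 1.4,
      ratio_lower = 0.54,
      ratio_upper = 2.0
    )
  )
}

#' Build a derivation config, optionally overriding defaults from JSON
#'
#' @param path Optional path to a JSON file whose entries override the
#'   matching entries of [default_constants()] (recursive merge; unknown keys
#'   are an error so typos never pass silently).
#' @param overrides Optional named list applied after the file, same rules.
#' @return The merged constants list.
#' @export
ffq_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_constants()
  if (!is.null(path)) {
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    cfg <- merge_config(cfg, user, "config")
  }
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides, "overrides")
  cfg
}

merge_config <- function(base, user, where) {
  if (!is.list(user)) stop("config section '", where, "' must be a mapping")
  for (key in names(user)) {
    if (!key %in% names(base)) {
      stop("unknown config key '", key, "' under '", where, "'")
    }
    if (is.list(base[[key]])) {
      base[[key]] <- merge_config(base[[key]], as.list(user[[key]]),
                                  paste(where, key, sep = "/"))
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

# Normalise a free-text category label: lower-case, collapse whitespace,
# en/em dashes to hyphens, trim. Keeps transcriptions like
# "1–3 times a week" and "1-3 Times A Week" equivalent.
normalise_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[–—]", "-", x)
  x <- gsub("’", "'", x)
  x <- gsub("\\s+", " ", x)
  x <- gsub("\\s*-\\s*", "-", x)
  # the frequency scale is printed both as "times a week" and "times per week"
  x <- gsub(" times per week", " times a week", x, fixed = TRUE)
  x
}
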
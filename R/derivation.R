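#' Recode a weekly frequency category to times per week
#'
#' The five response options map to 0, 0.5, 2, 5.5 and 10 times per week; an
#' unanswered question is treated as the food being rarely or never eaten
#' (weight 0). Labels are matched after normalisation (case, whitespace,
#' dash style, "per week"/"a week").
#'
#' @param x Character vector of category labels (NA for missing).
#' @param weights Named weight list, default the packaged values.
#' @return Numeric vector of times per week.
#' @export
recode_frequency <- function(x, weights = default_constants()$frequency_weights) {
  x <- as.character(x)
  out <- numeric(length(x))
  miss <- is.na(x)
  out[miss] <- weights$missing
  if (any(!miss)) {
    lab <- normalise_label(x[!miss])
    known <- setdiff(names(weights), "missing")
    bad <- setdiff(unique(lab), known)
    if (length(bad)) {
      stop("unknown frequency label(s): ", paste(bad, collapse = ", "))
    }
    out[!miss] <- unlist(weights[lab], use.names = FALSE)
  }
  out
}

#' Construct a nutrient vector
#'
#' @param values Named numeric vector; names must be exactly
#'   [nutrient_slots()] (any order; stored canonically). All values must be
#'   finite and non-negative.
#' @param basis "weekly" or "daily".
#' @return Object of class \code{nutrient_vector}.
#' @export
nutrient_vector <- function(values, basis = c("weekly", "daily")) {
  basis <- match.arg(basis)
  slots <- nutrient_slots()
  if (!setequal(names(values), slots)) {
    stop("nutrient vector must have exactly the canonical slots")
  }
  values <- values[slots]
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("nutrient values must be finite and >= 0")
  }
  structure(values, basis = basis, class = "nutrient_vector")
}

#' Convert a weekly nutrient vector to daily intakes
#'
#' Exact division of every slot by 7. Energy is carried in kJ; use
#' [energy_mj()] for the megajoule scale the daily summaries are reported on.
#'
#' @param v A weekly \code{nutrient_vector}.
#' @return A daily \code{nutrient_vector}.
#' @export
to_daily <- function(v) {
  stopifnot(inherits(v, "nutrient_vector"))
  if (attr(v, "basis") != "weekly") stop("vector is already on a daily basis")
  nutrient_vector(unclass(v) / 7, basis = "daily")
}

#' Energy of a nutrient vector in MJ
#'
#' @param v A \code{nutrient_vector}.
#' @return Energy in MJ on the vector's basis.
#' @export
energy_mj <- function(v) {
  stopifnot(inherits(v, "nutrient_vector"))
  unname(unclass(v)["energy_kj"] / 1000)
}

#' Load plausibility exclusion rules
#'
#' Reads the packaged JSON transcription of the intake plausibility bounds
#' (or a file in the same format): per rule a nutrient slot, optional strict
#' lower/upper bound, and the basis the bound is expressed on. The energy
#' rule is a weekly-kJ window (15000-120000); the remaining bounds are upper
#' limits on the daily scale in the output units.
#'
#' @param path JSON path; default the packaged rules.
#' @return Data frame with name, slot, basis, lower, upper.
#' @export
load_exclusion_rules <- function(path = ffqkit_extdata("exclusion_rules.json")) {
  obj <- jsonlite::read_json(path)
  rules <- do.call(rbind, lapply(obj$rules, function(r) {
    data.frame(name = r$name, slot = r$slot, basis = r$basis,
               lower = if (is.null(r$lower)) NA_real_ else r$lower,
               upper = if (is.null(r$upper)) NA_real_ else r$upper,
               stringsAsFactors = FALSE)
  }))
  bad <- setdiff(rules$slot, nutrient_slots())
  if (length(bad)) stop("exclusion rule references unknown slot(s): ",
                        paste(bad, collapse = ", "))
  both <- !is.na(rules$lower) & !is.na(rules$upper)
  if (any(both & rules$lower >= rules$upper)) stop("rule lower >= upper")
  if (!all(rules$basis %in% c("weekly", "daily"))) stop("rule basis must be weekly or daily")
  rules
}

#' Apply plausibility exclusion rules to a weekly nutrient vector
#'
#' A record is kept only if, for every rule, the value on the rule's basis
#' lies strictly inside the stated bounds; violating any single rule flags
#' the whole record for removal from the nutrient output.
#'
#' @param v Weekly \code{nutrient_vector}.
#' @param rules Data frame from [load_exclusion_rules()].
#' @return List with \code{kept} (logical) and \code{violated} (character
#'   vector of rule names suffixed \code{_low}/\code{_high}).
#' @export
apply_exclusions <- function(v, rules = load_exclusion_rules()) {
  stopifnot(inherits(v, "nutrient_vector"), attr(v, "basis") == "weekly")
  bad <- setdiff(rules$slot, nutrient_slots())
  if (length(bad)) stop("exclusion rule references unknown slot(s): ",
                        paste(bad, collapse = ", "))
  weekly <- unclass(v)
  violated <- character(0)
  for (i in seq_len(nrow(rules))) {
    val <- weekly[[rules$slot[i]]]
    if (rules$basis[i] == "daily") val <- val / 7
    if (!is.na(rules$lower[i]) && val <= rules$lower[i]) {
      violated <- c(violated, paste0(rules$name[i], "_low"))
    }
    if (!is.na(rules$upper[i]) && val >= rules$upper[i]) {
      violated <- c(violated, paste0(rules$name[i], "_high"))
    }
  }
  list(kept = length(violated) == 0, violated = violated)
}

# ---- daily basics -----------------------------------------------------------

# map from bread/fat/milk type answer codes to the portion-table question
# holding that type's composition blend
bread_type_questions <- c(c252 = "c7a", c253 = "c7b", c254 = "c7c", c255 = "c7d")
spread_type_questions <- c(c260 = "c8a", c261 = "c8b", c262 = "c8c",
                           c263 = "c8d", c264 = "c8e", c265 = "c8f")
cooking_type_questions <- c(c266 = "c8a_cooking", c267 = "c8b", c268 = "c8c",
                            c269 = "c8d", c270 = "c8e", c271 = "c8f")
milk_type_questions <- c(c276 = "c10a", c277 = "c10b", c278 = "c10c",
                         c279 = "c10d", c280 = "c10a", c281 = "c10f",
                         c282 = "c10g", c283 = "c10a")

type_shares <- function(row, codes, weights, fallback) {
  w <- vapply(names(codes), function(code) {
    a <- answer_of(row, code)
    key <- if (is.na(a)) "missing" else normalise_label(a)
    if (!key %in% names(weights)) {
      stop("unrecognised type answer for ", code, ": ", a)
    }
    as.numeric(weights[[key]])
  }, numeric(1))
  # several type codes can share one composition question (e.g. dried milk
  # carried as whole milk); aggregate before renormalising
  agg <- tapply(w, codes[names(w)], sum)
  if (sum(agg) == 0) {
    agg <- stats::setNames(numeric(length(agg)), names(agg))
    agg[fallback] <- 1
    if (is.na(agg[fallback])) agg <- stats::setNames(1, fallback)
  }
  shares <- agg / sum(agg)
  shares <- shares[shares > 0]
  stats::setNames(as.numeric(shares), names(shares))
}

#' Resolve the daily-basics answers of one participant
#'
#' Applies the version-6 recodes and share logic for the eight daily foods:
#' bread-slice categories map to their midpoints (<1, 1-2, 3-4, >=5 become
#' 0.5, 1.5, 3.5, 5.5 slices/day) with missing recoded to 1.5; slices spread
#' with fat default to 2 when missing and cap at 6; soft drinks carry a fixed
#' frequency of 2/week with the diet-drink answer scaling the sugary
#' fraction; type ticks are weighted (usually 1, sometimes 0.5, plain yes 1)
#' and renormalised to shares, falling back to the national-default type
#' (white bread, whole milk, soft margarine, vegetable oil) when nothing is
#' ticked. This stage is total: it never fails on a schema-valid response.
#'
#' @param row One participant's answers (a row of an \code{ffq_responses},
#'   as a named list).
#' @param config Constants list from [ffq_config()].
#' @return List of resolved basics (slices, shares, milk use volumes, sugar
#'   spoons, drink counts, soft-drink settings).
#' @export
resolve_basics <- function(row, config = default_constants()) {
  num_answer <- function(code, default = 0) {
    a <- answer_of(row, code)
    if (is.na(a)) return(default)
    v <- suppressWarnings(as.numeric(a))
    if (is.na(v) || v < 0) default else v
  }

  # bread slices/day from the categorical answer
  bread_cat <- answer_of(row, "c250")
  slices_map <- config$bread$slices_by_category
  if (is.na(bread_cat)) {
    bread_slices <- config$bread$missing_slices
  } else {
    key <- normalise_label(bread_cat)
    if (!key %in% names(slices_map)) {
      stop("unrecognised bread-slices category: ", bread_cat)
    }
    bread_slices <- as.numeric(slices_map[[key]])
  }
  no_bread <- identical(answer_of(row, "c256"), "yes")
  if (no_bread) bread_slices <- 0

  # slices spread with fat/day: missing -> 2, capped at 6
  spread_a <- answer_of(row, "c275")
  spread_slices <- if (is.na(spread_a)) config$spread$missing_slices else {
    v <- suppressWarnings(as.numeric(spread_a))
    if (is.na(v) || v < 0) config$spread$missing_slices else v
  }
  spread_slices <- min(spread_slices, config$spread$max_slices)

  tw <- config$type_weights
  bread_shares <- if (no_bread) stats::setNames(numeric(0), character(0)) else
    type_shares(row, bread_type_questions, tw, "c7a")
  spread_shares <- type_shares(row, spread_type_questions, tw, "c8b")
  cooking_shares <- type_shares(row, cooking_type_questions, tw, "c8f")
  milk_shares <- type_shares(row, milk_type_questions, config$milk$use_weights, "c10a")

  # daily milk volume over the six uses
  use_codes <- c(tea = "c284", coffee = "c285", cereal = "c286",
                 pudding = "c287", drink = "c288", milky_drink = "c289")
  uw <- config$milk$use_weights
  milk_ml <- sum(vapply(names(use_codes), function(use) {
    a <- answer_of(row, use_codes[[use]])
    key <- if (is.na(a)) "missing" else normalise_label(a)
    if (!key %in% names(uw)) stop("unrecognised milk-use answer: ", a)
    as.numeric(uw[[key]]) * as.numeric(config$milk$use_volumes_ml[[use]])
  }, numeric(1)))

  # soft drinks: fixed weekly frequency, diet-drink answer scales the
  # sugary fraction
  diet_a <- answer_of(row, "c247")
  sf <- config$soft_drinks$sugary_fraction
  key <- if (is.na(diet_a)) "missing" else normalise_label(diet_a)
  if (!key %in% names(sf)) stop("unrecognised diet-drink answer: ", diet_a)

  list(
    bread_slices_per_day = bread_slices,
    spread_slices_per_day = spread_slices,
    bread_shares = bread_shares,
    spread_shares = spread_shares,
    cooking_shares = cooking_shares,
    milk_shares = milk_shares,
    milk_ml_per_day = milk_ml,
    sugar_spoons_tea = num_answer("c302"),
    sugar_spoons_coffee = num_answer("c306"),
    cups_tea_per_day = num_answer("c300") + num_answer("c301"),
    cups_coffee_per_day = num_answer("c304") + num_answer("c305"),
    cups_tea_caffeinated = num_answer("c300"),
    cups_coffee_caffeinated = num_answer("c304"),
    colas_caffeinated = num_answer("c310"),
    colas_decaffeinated = num_answer("c311"),
    soft_drink_freq_per_week = config$soft_drinks$frequency_per_week,
    soft_drink_sugary_fraction = as.numeric(sf[[key]])
  )
}

# ---- per-question nutrient profiles -----------------------------------------

# Per consumption occasion of `question`, the nutrient amount per slot,
# honouring nutrient-specific alternates (slot s reads the alternate list
# tagged for s when one exists, else the default).
question_profile <- function(portions, composition, question,
                             behaviour = NULL) {
  slots <- composition_slots()
  rows <- portions[portions$question_id == question, , drop = FALSE]
  if (!nrow(rows)) stop("unknown question in portion table: ", question)
  tags <- unique(rows$variant)
  if (any(tags %in% c("fat_all", "fat_some", "fat_none"))) {
    tag <- behaviour_variant(behaviour)
    comp <- rows[rows$variant == tag, , drop = FALSE]
    return(portion_nutrients(comp, composition))
  }
  prof <- portion_nutrients(rows[rows$variant == "default", , drop = FALSE],
                            composition)
  map <- variant_slot_map()
  for (tag in intersect(tags, names(map))) {
    alt <- portion_nutrients(rows[rows$variant == tag, , drop = FALSE],
                             composition)
    covered <- intersect(map[[tag]], slots)
    prof[covered] <- alt[covered]
  }
  prof
}

# Precompute profiles for all questions; behaviour questions get one profile
# per behaviour variant.
build_profiles <- function(portions, composition) {
  qs <- unique(portions$question_id)
  profiles <- list()
  for (q in qs) {
    tags <- unique(portions$variant[portions$question_id == q])
    if (any(tags %in% c("fat_all", "fat_some", "fat_none"))) {
      profiles[[q]] <- list(
        fat_all = question_profile(portions, composition, q, "yes, all of it"),
        fat_some = question_profile(portions, composition, q, "yes, some of it"),
        fat_none = question_profile(portions, composition, q, "no")
      )
    } else {
      profiles[[q]] <- question_profile(portions, composition, q)
    }
  }
  profiles
}

# ---- weekly summation -------------------------------------------------------

#' Weekly nutrient intake of one participant
#'
#' The engine of the derivation: each weekly frequency question contributes
#' (recoded times/week) x (portion nutrient profile); the daily basics add
#' bread (slices/day x 7 x per-slice type blend), spreading fat
#' (spread slices/day x 7 x per-slice fat amount x type blend), milk (summed
#' daily use volumes x 7 x type blend), sugar in tea and coffee
#' (spoons x cups x 7 x per-spoon weight) and soft drinks (fixed 2/week x
#' portion x sugary fraction). The fish fatty-acid and caffeine slots come
#' from their closed-form estimators.
#'
#' @param row One participant's answers as a named list.
#' @param portions A [load_portion_table()] result.
#' @param composition A [load_composition()] table.
#' @param config Constants from [ffq_config()].
#' @param schema The [ffq_schema()].
#' @param profiles Optional precomputed [build_profiles()] output (pass when
#'   deriving a whole cohort; computed on the fly otherwise).
#' @return A weekly \code{nutrient_vector}.
#' @export
weekly_nutrients <- function(row, portions, composition,
                             config = default_constants(),
                             schema = ffq_schema(),
                             profiles = NULL) {
  if (is.null(profiles)) profiles <- build_profiles(portions, composition)
  slots <- composition_slots()
  total <- stats::setNames(numeric(length(slots)), slots)
  basics <- resolve_basics(row, config)
  behaviour <- answer_of(row, "c221")

  # weekly frequency questions (those with a portion block)
  witems <- schema$items[schema$items$scale == "weekly5", , drop = FALSE]
  for (i in seq_len(nrow(witems))) {
    q <- witems$question_id[i]
    prof <- profiles[[q]]
    if (is.null(prof)) next  # behaviour-only item (fried foods)
    freq <- recode_frequency(answer_of(row, witems$code[i]),
                             config$frequency_weights)
    if (freq == 0) next
    if (is.list(prof)) prof <- prof[[behaviour_variant(behaviour)]]
    total <- total + freq * prof
  }

  # bread: slices/day x 7, blended over bread-type shares
  if (basics$bread_slices_per_day > 0 && length(basics$bread_shares)) {
    slice <- Reduce(`+`, Map(function(q, s) s * profiles[[q]],
                             names(basics$bread_shares), basics$bread_shares))
    total <- total + basics$bread_slices_per_day * 7 * slice
  }

  # spreading fat: fat-type profiles are per-100g blends
  if (basics$spread_slices_per_day > 0) {
    blend <- Reduce(`+`, Map(function(q, s) s * profiles[[q]],
                             names(basics$spread_shares), basics$spread_shares))
    total <- total + basics$spread_slices_per_day * 7 *
      (config$spread$grams_per_slice / 100) * blend
  }

  # milk: type profiles are per 100 g; 1 ml taken as 1 g
  if (basics$milk_ml_per_day > 0) {
    blend <- Reduce(`+`, Map(function(q, s) s * profiles[[q]],
                             names(basics$milk_shares), basics$milk_shares))
    total <- total + basics$milk_ml_per_day * 7 / 100 * blend
  }

  # sugar in tea and coffee
  sugar_g_per_day <- config$sugar$grams_per_spoon *
    (basics$sugar_spoons_tea * basics$cups_tea_per_day +
       basics$sugar_spoons_coffee * basics$cups_coffee_per_day)
  if (sugar_g_per_day > 0) {
    sugar_comp <- portion_nutrients(
      data.frame(food_code = as.character(config$sugar$food_code), grams = 100),
      composition)
    total <- total + sugar_g_per_day * 7 / 100 * sugar_comp
  }

  # soft drinks: fixed frequency, average drink rescaled to the configured
  # portion weight, sugary fraction from the diet-drink answer
  if (basics$soft_drink_sugary_fraction > 0) {
    comp <- portion_for(portions, "c4")
    scale <- config$soft_drinks$portion_g / sum(comp$grams)
    drink <- portion_nutrients(comp, composition) * scale
    total <- total + basics$soft_drink_freq_per_week *
      basics$soft_drink_sugary_fraction * drink
  }

  # closed-form streams
  fish <- fish_fatty_acids(
    freq_white = recode_frequency(answer_of(row, "c205"), config$frequency_weights),
    freq_oily  = recode_frequency(answer_of(row, "c206"), config$frequency_weights),
    freq_shell = recode_frequency(answer_of(row, "c207"), config$frequency_weights),
    config = config, basis = "weekly")
  caffeine <- caffeine_weekly(
    cups_tea = basics$cups_tea_caffeinated,
    cups_coffee = basics$cups_coffee_caffeinated,
    colas = basics$colas_caffeinated,
    config = config)

  full <- c(total,
            n3_fish_g = unname(fish["n3"]),
            dha_fish_g = unname(fish["dha"]),
            epa_fish_g = unname(fish["epa"]),
            caffeine_mg = caffeine)
  nutrient_vector(full, basis = "weekly")
}

#' Derive daily nutrient intakes for a whole cohort
#'
#' Runs the full pipeline: weekly summation per participant, plausibility
#' exclusions on the weekly totals, division by 7 to the daily basis. The
#' n-3 output stream carries its own (by default empty) screen through
#' \code{n3_rules}, mirroring the separately maintained fish fatty-acid file.
#'
#' @param responses An \code{ffq_responses} cohort.
#' @inheritParams weekly_nutrients
#' @param rules Exclusion rules from [load_exclusion_rules()]; NULL to skip.
#' @param n3_rules Optional rules applied only to the fish fatty-acid slots'
#'   output stream (default none are defined).
#' @param keep_excluded Keep excluded participants in the daily table
#'   (flagged) instead of dropping them.
#' @return List with \code{daily} (data frame, one row per kept participant:
#'   participant_id, energy_mj, then all slots per day), \code{weekly}
#'   (matrix of weekly totals for all participants), \code{exclusions}
#'   (data frame participant_id, rules) and \code{n3_exclusions}.
#' @export
derive_nutrients <- function(responses, portions = load_portion_table(),
                             composition = load_composition(),
                             rules = load_exclusion_rules(),
                             n3_rules = NULL,
                             config = default_constants(),
                             schema = ffq_schema(),
                             keep_excluded = FALSE) {
  stopifnot(inherits(responses, "ffq_responses"))
  profiles <- build_profiles(portions, composition)
  n <- nrow(responses)
  ids <- as.data.frame(responses)$participant_id
  weekly <- matrix(0, n, length(nutrient_slots()),
                   dimnames = list(ids, nutrient_slots()))
  kept <- rep(TRUE, n)
  excl <- list()
  n3_excl <- list()
  for (i in seq_len(n)) {
    v <- weekly_nutrients(response_row(responses, i), portions, composition,
                          config, schema, profiles)
    weekly[i, ] <- unclass(v)
    if (!is.null(rules)) {
      res <- apply_exclusions(v, rules)
      if (!res$kept) {
        kept[i] <- FALSE
        excl[[ids[i]]] <- res$violated
      }
    }
    if (!is.null(n3_rules)) {
      res3 <- apply_exclusions(v, n3_rules)
      if (!res3$kept) n3_excl[[ids[i]]] <- res3$violated
    }
  }
  daily_rows <- if (keep_excluded) seq_len(n) else which(kept)
  daily_mat <- weekly[daily_rows, , drop = FALSE] / 7
  daily <- data.frame(participant_id = ids[daily_rows],
                      energy_mj = daily_mat[, "energy_kj"] / 1000,
                      daily_mat, row.names = NULL, check.names = FALSE,
                      stringsAsFactors = FALSE)
  if (keep_excluded) daily$excluded <- !kept
  as_log <- function(x) data.frame(
    participant_id = if (length(x)) names(x) else character(0),
    rules = vapply(x, paste, character(1), collapse = ";"),
    row.names = NULL, stringsAsFactors = FALSE)
  exclusions <- as_log(excl)
  n3_exclusions <- as_log(n3_excl)
  list(daily = daily, weekly = weekly, exclusions = exclusions,
       n3_exclusions = n3_exclusions)
}
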
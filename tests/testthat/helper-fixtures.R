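# Shared fixtures: tiny hand-checkable tables, a mid-range weekly intake, and
# an independent re-implementation of the weekly summation used as the oracle
# in equivalence tests.

# toy composition table: two foods with simple densities, written to a temp
# CSV so the loader path is exercised too
toy_composition <- function(densities = c(a = 5, b = 4)) {
  slots <- composition_slots()
  df <- data.frame(food_code = names(densities),
                   description = paste("toy", names(densities)))
  for (s in slots) df[[paste0(s, "_per100g")]] <- 0
  df$energy_kj_per100g <- as.numeric(densities)
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  load_composition(path)
}

# a weekly nutrient vector sitting comfortably inside every plausibility
# bound (values shaped like a typical cohort mean, on the weekly scale)
plausible_weekly <- function() {
  daily <- c(
    energy_kj = 7230, protein_g = 69.3, fat_g = 71, satfat_g = 30,
    mufa_g = 24, pufa_g = 12.3, cholesterol_mg = 217, carbohydrate_g = 213,
    starch_g = 116, sugars_g = 96, nmes_g = 61, nsp_g = 14.9,
    calcium_mg = 938, potassium_mg = 2879, sodium_mg = 2193,
    phosphorus_mg = 1247, magnesium_mg = 247, folate_ug = 243,
    iron_mg = 10.2, zinc_mg = 8.2, vitamin_c_mg = 79.5, thiamin_mg = 1.43,
    riboflavin_mg = 1.7, retinol_ug = 367, vitamin_e_mg = 8.5,
    vitamin_d_ug = 3.8, vitamin_b6_mg = 1.9, vitamin_b12_ug = 4.9,
    niacin_eq_mg = 30.3, niacin_mg = 15.9, tryptophan_mg = 14.4,
    carotene_ug = 2128, selenium_ug = 70.6, iodine_ug = 148,
    n3_fish_g = 0.15, dha_fish_g = 0.07, epa_fish_g = 0.05,
    caffeine_mg = 25)
  nutrient_vector(daily * 7, basis = "weekly")
}

# ---------------------------------------------------------------------------
# Independent oracle: recomputes one participant's weekly nutrient totals
# straight from the raw CSV fixtures with its own label maps, variant
# resolution and basics arithmetic. Deliberately written as plain loops over
# question and component food so it shares no code with weekly_nutrients().

oracle_env <- new.env()

oracle_tables <- function() {
  if (!is.null(oracle_env$pt)) return(invisible(NULL))
  pt <- read.csv(system.file("extdata", "portion_table.csv", package = "ffqkit"),
                 colClasses = c(food_code = "character"))
  comp <- read.csv(system.file("extdata", "composition_synthetic.csv",
                               package = "ffqkit"), check.names = FALSE)
  comp$food_code <- as.character(comp$food_code)
  oracle_env$pt <- pt
  oracle_env$comp <- comp
  invisible(NULL)
}

oracle_freq <- function(label) {
  if (is.na(label)) return(0)
  key <- gsub("–", "-", tolower(label))
  switch(key,
         "never or rarely" = 0, "once in 2 weeks" = 0.5,
         "1-3 times a week" = 2, "4-7 times a week" = 5.5,
         "more than once a day" = 10,
         stop("oracle: bad label ", label))
}

oracle_variant_map <- list(
  vitaminE = "vitamin_e_mg", vitaminC = "vitamin_c_mg", folate = "folate_ug",
  retinol = "retinol_ug", carotene = "carotene_ug", zinc = "zinc_mg",
  pyridoxine = "vitamin_b6_mg", niacin = "niacin_mg",
  fattyAcids = c("satfat_g", "mufa_g", "pufa_g"),
  totalFatEnergy = c("fat_g", "energy_kj"))

# nutrient content of one occasion of `question` for slot `slot`; cached by
# (question, slot, behaviour tag) since the tables are fixed within a run
oracle_portion_amount <- function(question, slot, behaviour) {
  btag <- if (is.null(behaviour) || is.na(behaviour)) "." else tolower(behaviour)
  key <- paste(question, slot, btag, sep = "|")
  if (is.null(oracle_env$cache)) oracle_env$cache <- new.env()
  hit <- get0(key, envir = oracle_env$cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  val <- oracle_portion_amount_raw(question, slot, behaviour)
  assign(key, val, envir = oracle_env$cache)
  val
}

oracle_portion_amount_raw <- function(question, slot, behaviour) {
  pt <- oracle_env$pt; comp <- oracle_env$comp
  rows <- pt[pt$question_id == question, ]
  tags <- unique(rows$variant)
  if (any(grepl("^fat_", tags))) {
    tag <- if (is.na(behaviour)) "fat_all" else
      switch(tolower(behaviour), "yes, all of it" = "fat_all",
             "yes, some of it" = "fat_some", "fat_none")
  } else {
    tag <- "default"
    for (t in tags) {
      covered <- oracle_variant_map[[t]]
      if (!is.null(covered) && slot %in% covered) tag <- t
    }
  }
  rows <- rows[rows$variant == tag, ]
  amount <- 0
  for (r in seq_len(nrow(rows))) {        # loop over component foods
    dens <- comp[comp$food_code == rows$food_code[r],
                 paste0(slot, "_per100g")]
    amount <- amount + rows$grams[r] / 100 * dens
  }
  amount
}

# map a "usually/sometimes/no" answer to a weight
oracle_tick <- function(a) {
  if (is.na(a)) return(0)
  switch(tolower(a), "yes usually" = 1, "yes" = 1, "yes sometimes" = 0.5, 0)
}

oracle_shares <- function(row, codes, targets, fallback) {
  w <- sapply(seq_along(codes), function(i) oracle_tick(row[[codes[i]]]))
  agg <- tapply(w, targets, sum)
  if (sum(agg) == 0) { agg[] <- 0; agg[fallback] <- 1 }
  agg / sum(agg)
}

oracle_num <- function(row, code) {
  a <- row[[code]]
  if (is.null(a) || is.na(a)) return(0)
  v <- suppressWarnings(as.numeric(a))
  if (is.na(v) || v < 0) 0 else v
}

# full weekly totals for one response row (named list of raw answers)
oracle_weekly <- function(row) {
  oracle_tables()
  schema <- ffq_schema()
  slots <- composition_slots()
  qmap <- setNames(schema$items$question_id, schema$items$code)
  wcodes <- schema$items$code[schema$items$scale == "weekly5"]
  behaviour <- row[["c221"]]
  total <- setNames(numeric(length(slots)), slots)
  pt_questions <- unique(oracle_env$pt$question_id)
  for (code in wcodes) {                  # loop over questions
    q <- qmap[[code]]
    if (!q %in% pt_questions) next
    f <- oracle_freq(row[[code]])
    if (f == 0) next
    for (slot in slots) {                 # loop over nutrients
      total[slot] <- total[slot] +
        f * oracle_portion_amount(q, slot, behaviour)
    }
  }
  # bread
  slices <- if (is.na(row[["c250"]])) 1.5 else
    switch(tolower(gsub("–", "-", row[["c250"]])),
           "less than 1" = 0.5, "1-2" = 1.5, "3-4" = 3.5, "5 or more" = 5.5)
  if (identical(tolower(row[["c256"]]), "yes")) slices <- 0
  if (slices > 0) {
    sh <- oracle_shares(row, c("c252", "c253", "c254", "c255"),
                        c("c7a", "c7b", "c7c", "c7d"), "c7a")
    for (q in names(sh)) {
      if (sh[[q]] == 0) next
      for (slot in slots) {
        total[slot] <- total[slot] +
          slices * 7 * sh[[q]] * oracle_portion_amount(q, slot, NA)
      }
    }
  }
  # spreading fat
  spread <- row[["c275"]]
  spread <- if (is.na(spread)) 2 else min(max(0, suppressWarnings(as.numeric(spread))), 6)
  if (is.na(spread)) spread <- 2
  if (spread > 0) {
    sh <- oracle_shares(row, c("c260", "c261", "c262", "c263", "c264", "c265"),
                        c("c8a", "c8b", "c8c", "c8d", "c8e", "c8f"), "c8b")
    for (q in names(sh)) {
      if (sh[[q]] == 0) next
      for (slot in slots) {
        total[slot] <- total[slot] +
          spread * 7 * (7 / 100) * sh[[q]] * oracle_portion_amount(q, slot, NA)
      }
    }
  }
  # milk
  vols <- c(c284 = 30, c285 = 30, c286 = 100, c287 = 100, c288 = 200, c289 = 200)
  ml <- sum(sapply(names(vols), function(code) oracle_tick(row[[code]]) * vols[[code]]))
  if (ml > 0) {
    sh <- oracle_shares(row, paste0("c", 276:283),
                        c("c10a", "c10b", "c10c", "c10d", "c10a", "c10f",
                          "c10g", "c10a"), "c10a")
    for (q in names(sh)) {
      if (sh[[q]] == 0) next
      for (slot in slots) {
        total[slot] <- total[slot] +
          ml * 7 / 100 * sh[[q]] * oracle_portion_amount(q, slot, NA)
      }
    }
  }
  # sugar in tea and coffee
  sugar_g <- 5 * (oracle_num(row, "c302") * (oracle_num(row, "c300") + oracle_num(row, "c301")) +
                    oracle_num(row, "c306") * (oracle_num(row, "c304") + oracle_num(row, "c305")))
  if (sugar_g > 0) {
    for (slot in slots) {
      dens <- oracle_env$comp[oracle_env$comp$food_code == "8888",
                              paste0(slot, "_per100g")]
      total[slot] <- total[slot] + sugar_g * 7 / 100 * dens
    }
  }
  # soft drinks
  frac <- if (is.na(row[["c247"]])) 1 else
    switch(tolower(row[["c247"]]), "always" = 0, "sometimes" = 0.5,
           "not at all" = 1, 0)
  if (frac > 0) {
    for (slot in slots) {
      total[slot] <- total[slot] +
        2 * frac * (110 / 330) * oracle_portion_amount("c4", slot, NA)
    }
  }
  # closed-form slots
  fw <- oracle_freq(row[["c205"]]); fo <- oracle_freq(row[["c206"]])
  fs <- oracle_freq(row[["c207"]])
  caffeine <- 7 * (oracle_num(row, "c300") * 27 + oracle_num(row, "c304") * 57 +
                     oracle_num(row, "c310") * 20)
  c(total,
    n3_fish_g = fw * 0.32 + fo * 0.89 + fs * 0.35,
    dha_fish_g = fw * 0.16 + fo * 0.42 + fs * 0.16,
    epa_fish_g = fw * 0.10 + fo * 0.30 + fs * 0.12,
    caffeine_mg = caffeine)
}
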
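portions <- load_portion_table()
composition <- load_composition()

test_that("frequency recoding uses the printed weights and treats missing as never", {
  expect_equal(recode_frequency("4–7 times per week"), 5.5)
  expect_equal(recode_frequency("Once in 2 weeks"), 0.5)
  expect_equal(recode_frequency(c("Never or rarely", "1-3 times a week",
                                  "More than once a day", NA)),
               c(0, 2, 10, 0))
  expect_error(recode_frequency("twice a fortnight"), "unknown frequency")
  # weights are monotone over the ordered categories
  w <- recode_frequency(weekly5_labels())
  expect_false(is.unsorted(w, strictly = TRUE))
})

test_that("daily basics apply the version-6 recodes", {
  row <- list(participant_id = "x")
  b <- resolve_basics(row)
  expect_equal(b$bread_slices_per_day, 1.5)   # missing slices
  expect_equal(b$spread_slices_per_day, 2)    # missing spread slices
  expect_equal(b$soft_drink_freq_per_week, 2)
  # defaults: white bread, soft margarine, whole milk
  expect_equal(names(b$bread_shares), "c7a")
  expect_equal(names(b$spread_shares), "c8b")
  expect_equal(names(b$milk_shares), "c10a")

  row2 <- list(c250 = "3-4", c275 = "9")
  b2 <- resolve_basics(row2)
  expect_equal(b2$bread_slices_per_day, 3.5)
  expect_equal(b2$spread_slices_per_day, 6)   # capped at 6

  # milk: full fat usually + skimmed sometimes -> shares 2/3, 1/3
  row3 <- list(c276 = "yes usually", c278 = "yes sometimes")
  b3 <- resolve_basics(row3)
  expect_equal(unname(b3$milk_shares[c("c10a", "c10c")]), c(2 / 3, 1 / 3))

  # no-bread tick zeroes the bread stream
  b4 <- resolve_basics(list(c250 = "5 or more", c256 = "yes"))
  expect_equal(b4$bread_slices_per_day, 0)
})

test_that("a single answered food contributes frequency x portion composition", {
  # toy tables: one question, one food of 50 g at 6 kJ/100 g
  pt_path <- tempfile(fileext = ".csv")
  write.csv(data.frame(question_id = "c3a", variant = "default",
                       food_code = "a", description = "toy", grams = 50),
            pt_path, row.names = FALSE)
  toy_pt <- load_portion_table(pt_path)
  toy_comp <- toy_composition(c(a = 6))
  row <- list(c222 = "1-3 times a week",          # recodes to 2/week
              c256 = "yes", c275 = "0",           # no bread, no spread
              c247 = "don't drink soft drinks")   # no soft drinks
  v <- weekly_nutrients(row, toy_pt, toy_comp)
  expect_equal(unclass(v)[["energy_kj"]], 2 * 50 / 100 * 6)
  expect_true(all(unclass(v)[setdiff(nutrient_slots(), "energy_kj")] == 0))
})

test_that("an all-missing response yields exactly the basics defaults", {
  row <- list(participant_id = "x")
  v <- unclass(weekly_nutrients(row, portions, composition))
  bread <- portion_nutrients(portion_for(portions, "c7a"), composition)
  spread <- portion_nutrients(portion_for(portions, "c8b"), composition)
  # the spreading-fat blend reads its vitamin E from the tagged alternate
  spread["vitamin_e_mg"] <-
    portion_nutrients(portion_for(portions, "c8b", "vitamin_e_mg"),
                      composition)[["vitamin_e_mg"]]
  drink <- portion_nutrients(portion_for(portions, "c4"), composition)
  expected <- 1.5 * 7 * bread + 2 * 7 * (7 / 100) * spread +
    2 * (110 / sum(portion_for(portions, "c4")$grams)) * drink
  expect_equal(v[composition_slots()], expected, tolerance = 1e-12)
  expect_equal(v[["n3_fish_g"]], 0)
  expect_equal(v[["caffeine_mg"]], 0)
})

test_that("declining meat fat switches the contribution to the lean foods", {
  base <- list(c202 = "4-7 times a week", c256 = "yes", c275 = "0",
               c247 = "don't drink soft drinks")
  v_all <- weekly_nutrients(c(base, c221 = "Yes, all of it"), portions, composition)
  v_none <- weekly_nutrients(c(base, c221 = "No"), portions, composition)
  lean <- portion_nutrients(portion_for(portions, "c1c", behaviour = "No"),
                            composition)
  fat <- portion_nutrients(portion_for(portions, "c1c", behaviour = "Yes, all of it"),
                           composition)
  expect_equal(unclass(v_none) - unclass(v_all),
               c(5.5 * (lean - fat), n3_fish_g = 0, dha_fish_g = 0,
                 epa_fish_g = 0, caffeine_mg = 0), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("weekly totals convert to daily by exact division by seven", {
  v <- plausible_weekly()
  d <- to_daily(v)
  expect_equal(attr(d, "basis"), "daily")
  expect_equal(unclass(d), unclass(v) / 7, tolerance = 1e-15,
               ignore_attr = TRUE)
  expect_equal(energy_mj(d), 7.23, tolerance = 1e-12)
  expect_equal(unclass(d)[["protein_g"]], 485.1 / 7, tolerance = 1e-12)
  expect_error(to_daily(d), "already")
  zero <- nutrient_vector(setNames(numeric(38), nutrient_slots()), "weekly")
  expect_true(all(unclass(to_daily(zero)) == 0))
})

test_that("plausibility screening flags each printed bound", {
  rules <- load_exclusion_rules()
  expect_equal(nrow(rules), 18)
  base <- plausible_weekly()
  expect_true(apply_exclusions(base, rules)$kept)

  low <- unclass(base); low["energy_kj"] <- 14000
  res <- apply_exclusions(nutrient_vector(low, "weekly"), rules)
  expect_false(res$kept)
  expect_equal(res$violated, "energy_low")

  hi <- unclass(base); hi["retinol_ug"] <- 8100 * 7   # daily 8100 vs bound 8000
  res2 <- apply_exclusions(nutrient_vector(hi, "weekly"), rules)
  expect_false(res2$kept)
  expect_equal(res2$violated, "retinol_high")

  bad_rules <- rules; bad_rules$slot[1] <- "unobtainium"
  expect_error(apply_exclusions(base, bad_rules), "unknown slot")
})

test_that("raising any single frequency never decreases any nutrient", {
  set.seed(7)
  labels <- weekly5_labels()
  codes <- weekly_codes(ffq_schema())
  for (rep in 1:10) {
    code <- sample(codes, 1)
    lvl <- sample(4, 1)
    row_lo <- list(c256 = "yes", c275 = "0",
                   c247 = "don't drink soft drinks")
    row_lo[[code]] <- labels[lvl]
    row_hi <- row_lo
    row_hi[[code]] <- labels[lvl + 1]
    lo <- unclass(weekly_nutrients(row_lo, portions, composition))
    hi <- unclass(weekly_nutrients(row_hi, portions, composition))
    expect_true(all(hi - lo >= -1e-12))
  }
})

test_that("the cohort derivation is deterministic and splits exclusions out", {
  g <- generate_cohort(cohort_config(n = 40), seed = 9)
  d1 <- derive_nutrients(g$responses)
  d2 <- derive_nutrients(g$responses)
  expect_identical(d1$weekly, d2$weekly)
  expect_identical(d1$daily, d2$daily)
  expect_equal(nrow(d1$daily) + nrow(d1$exclusions), nrow(g$responses))
  expect_equal(d1$daily$energy_mj,
               d1$daily$energy_kj / 1000, tolerance = 1e-12)
})
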
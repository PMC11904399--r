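portions <- load_portion_table()
composition <- load_composition()

test_that("packaged portion assignments match the transcribed table", {
  bb <- portion_for(portions, "c3a")
  expect_equal(bb$food_code, "694")
  expect_equal(bb$grams, 135)
  crisps <- portion_for(portions, "c1q")
  expect_equal(crisps$food_code, "1037")
  expect_equal(crisps$grams, 27)
  # nutrient-specific alternate: bran cereals for vitamin C
  alt <- portion_for(portions, "c3m", "vitamin_c_mg")
  expect_equal(alt$food_code, c("65", "66", "90"))
  expect_equal(alt$grams, c(13, 10, 13))
  # no alternate for that nutrient -> default
  expect_equal(portion_for(portions, "c3a", "vitamin_c_mg")$food_code, "694")
  expect_error(portion_for(portions, "c99"), "unknown question")
})

test_that("fat-on-meat behaviour selects the printed meat variants", {
  all_fat <- portion_for(portions, "c1c", behaviour = "Yes, all of it")
  expect_setequal(all_fat$food_code, c("386", "412", "420", "358"))
  none <- portion_for(portions, "c1c", behaviour = "No")
  expect_setequal(none$food_code, c("387", "413", "422", "356"))
  some <- portion_for(portions, "c1c", behaviour = "Yes, Some of it")
  expect_equal(nrow(some), 8)          # half-weight lean + lean-and-fat rows
  expect_equal(sum(some$grams), 86)    # printed half-gram rows sum
  expect_setequal(some$food_code,
                  union(all_fat$food_code, none$food_code))
  # missing behaviour falls back to lean-and-fat; never-eats-meat to lean
  expect_setequal(portion_for(portions, "c1d", behaviour = NA)$food_code, "439")
  expect_setequal(portion_for(portions, "c1d", behaviour = "Never eat meat")$food_code,
                  "438")
})

test_that("portion table loading enforces variants, defaults and duplicates", {
  path <- tempfile(fileext = ".csv")
  df <- data.frame(question_id = "q1", variant = "vitaminQ",
                   food_code = "1", description = "x", grams = 10)
  write.csv(df, path, row.names = FALSE)
  expect_error(load_portion_table(path), "unrecognised portion-variant")
  df <- data.frame(question_id = "q1", variant = "vitaminE",
                   food_code = "1", description = "x", grams = 10)
  write.csv(df, path, row.names = FALSE)
  expect_error(load_portion_table(path), "without a default")
  df <- data.frame(question_id = "q1", variant = "default",
                   food_code = c("1", "1"), description = "x", grams = 10)
  write.csv(df, path, row.names = FALSE)
  expect_error(load_portion_table(path), "duplicate")
})

test_that("portion nutrient summation is the exact gram-weighted density sum", {
  comp <- toy_composition(c(a = 5, b = 4))
  one <- data.frame(food_code = "a", grams = 100)
  expect_equal(unname(portion_nutrients(one, comp)["energy_kj"]), 5)
  two <- data.frame(food_code = c("a", "b"), grams = c(50, 50))
  # 0.5*5 + 0.5*4, but with densities 2 and 4 the hand sum is 3
  comp2 <- toy_composition(c(a = 2, b = 4))
  expect_equal(unname(portion_nutrients(two, comp2)["energy_kj"]), 3)
  empty <- data.frame(food_code = character(0), grams = numeric(0))
  expect_true(all(portion_nutrients(empty, comp) == 0))
  expect_error(portion_nutrients(data.frame(food_code = "zz", grams = 1), comp),
               "zz")
})

test_that("portion nutrients are linear in the gram weights", {
  set.seed(11)
  for (rep in 1:5) {
    comps <- portion_for(portions, sample(c("c3b", "c1f", "c3h", "c3o"), 1))
    base <- portion_nutrients(comps, composition)
    doubled <- comps; doubled$grams <- doubled$grams * 2
    expect_equal(portion_nutrients(doubled, composition), 2 * base,
                 tolerance = 1e-12)
  }
})

test_that("every portioned question resolves a non-empty list for every nutrient", {
  qs <- setdiff(unique(portions$question_id), character(0))
  for (q in qs) {
    for (slot in composition_slots()) {
      comps <- portion_for(portions, q, slot, behaviour = "Yes, all of it")
      expect_gt(nrow(comps), 0)
      expect_true(all(comps$grams > 0))
    }
  }
})

test_that("fish mixes total the printed class weights", {
  mix <- load_fish_mix()
  expect_equal(total_portion_grams(mix, "white"), 130)
  expect_equal(total_portion_grams(mix, "shellfish"), 89)
  expect_equal(total_portion_grams(mix, "oily"), 108)
  expect_equal(total_portion_grams(mix, "plankton"), 0)
})

test_that("the packaged composition table covers every portioned food code", {
  expect_true(all(unique(portions$food_code) %in% composition$codes))
  expect_true(all(composition$densities >= 0))
})
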
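test_that("the packaged schema has 43 weekly-frequency items with unique codes", {
  s <- ffq_schema()
  expect_equal(count_weekly_items(s), 43)
  expect_false(anyDuplicated(s$items$code) > 0)
  expect_false(anyDuplicated(s$items$question_id) > 0)
  # the weekly block spans the documented code ranges
  wc <- s$items$code[s$items$scale == "weekly5"]
  expect_true(all(wc %in% c(paste0("c", 200:211), paste0("c", 215:220),
                            paste0("c", 222:246))))
  # a schema with no items counts zero
  empty <- structure(list(items = s$items[0, ], version = "x"),
                     class = "ffq_schema")
  expect_equal(count_weekly_items(empty), 0)
})

test_that("response loading validates columns, ids and labels", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("participant_id,c200,c222",
               "p1,Never or rarely,1–3 times a week",
               "p2,,4-7 Times Per Week"), path)
  r <- load_responses(path)
  expect_s3_class(r, "ffq_responses")
  expect_equal(nrow(r), 2)
  # case-insensitive, dash- and wording-tolerant label matching
  expect_equal(as.data.frame(r)$c222, c("1-3 times a week", "4-7 times a week"))
  expect_true(is.na(as.data.frame(r)$c200[2]))

  writeLines(c("participant_id,c999", "p1,x"), path)
  expect_error(load_responses(path), "c999")
  writeLines(c("participant_id,c200", "p1,Never or rarely", "p1,"), path)
  expect_error(load_responses(path), "duplicate participant_id")
  writeLines(c("participant_id,c200", "p1,sometimes-ish"), path)
  expect_warning(r2 <- load_responses(path), "unparseable")
  expect_true(is.na(as.data.frame(r2)$c200[1]))
})

test_that("responses survive a load-write-load round trip", {
  df <- data.frame(participant_id = c("a", "b"),
                   c200 = c("never or rarely", NA),
                   c250 = c("1-2", "5 or more"),
                   c275 = c("3", NA), stringsAsFactors = FALSE)
  r <- ffq_responses(df)
  path <- tempfile(fileext = ".csv")
  write_responses(r, path)
  r2 <- load_responses(path)
  expect_identical(as.data.frame(r), as.data.frame(r2))
})

test_that("nutrient tables round-trip through text and route exclusions to the log", {
  v <- plausible_weekly()
  records <- list(p1 = v, p2 = nutrient_vector(unclass(v) * 1.1, "weekly"))
  path <- tempfile(fileext = ".csv")
  write_nutrients(records, path)
  back <- read_nutrients(path)
  expect_equal(names(back), c("p1", "p2"))
  expect_equal(unclass(back$p1), unclass(v), tolerance = 1e-12)
  expect_equal(attr(back$p2, "basis"), "weekly")

  # a record violating the weekly energy floor lands in the exclusion log,
  # not the main file
  low <- unclass(v); low["energy_kj"] <- 14000
  bad <- nutrient_vector(low, "weekly")
  res <- apply_exclusions(bad)
  expect_false(res$kept)
  excl <- data.frame(participant_id = "p3",
                     rules = paste(res$violated, collapse = ";"))
  out <- write_nutrients(c(records, list(p3 = bad)), path, exclusions = excl)
  main <- read.csv(path)
  expect_false("p3" %in% main$participant_id)
  log <- read.csv(out$exclusion_log)
  expect_equal(log$participant_id, "p3")
  expect_match(log$rules, "energy_low")

  # empty record list gives a header-only file
  write_nutrients(setNames(list(), character(0)), path)
  expect_equal(nrow(read.csv(path)), 0)

  # mixed bases are a contract error
  expect_error(write_nutrients(list(a = v, b = to_daily(v)), path), "bases")
})

test_that("config overrides merge recursively and reject unknown keys", {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(caffeine = list(mg_per_cup_tea = 30)), path,
                       auto_unbox = TRUE)
  cfg <- ffq_config(path)
  expect_equal(cfg$caffeine$mg_per_cup_tea, 30)
  expect_equal(cfg$caffeine$mg_per_cup_coffee, 57)
  jsonlite::write_json(list(caffeine = list(mg_per_cup = 1)), path,
                       auto_unbox = TRUE)
  expect_error(ffq_config(path), "unknown config key")
})
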
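make_freq_matrix <- function(n = 200, seed = 5) {
  set.seed(seed)
  L <- default_pattern_loadings()
  s <- matrix(rnorm(n * 5), n, 5)
  mu <- default_item_means <- rep(1, nrow(L))
  x <- matrix(mu, n, nrow(L), byrow = TRUE) + s %*% t(L) +
    matrix(rnorm(n * nrow(L), 0, 0.3), n)
  colnames(x) <- rownames(L)
  pmax(x, 0)
}

test_that("pattern fitting is deterministic with centred scores and orthonormal loadings", {
  x <- make_freq_matrix()
  m <- fit_patterns(x, k = 5)
  s <- score_patterns(m, x)
  expect_equal(ncol(s), 5)
  expect_true(all(abs(colMeans(s)) < 1e-8))
  # orthonormal loading basis; varimax preserves the retained subspace
  expect_equal(crossprod(m$loadings), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  m2 <- fit_patterns(x, k = 5)
  expect_equal(m$loadings, m2$loadings)
  none <- fit_patterns(x, k = 5, rotate = "none")
  expect_equal(sum(apply(score_patterns(none, x), 2, var)),
               sum(apply(s, 2, var)), tolerance = 1e-8)
})

test_that("scoring is the standardised projection", {
  x <- make_freq_matrix(n = 120)
  m <- fit_patterns(x, k = 3)
  # the training-mean profile scores zero everywhere
  mean_row <- matrix(m$center, 1, dimnames = list(NULL, m$items))
  expect_equal(unname(score_patterns(m, mean_row)[1, ]), rep(0, 3),
               tolerance = 1e-10)
  # one SD above the mean on a single item reproduces that item's loading row
  j <- 4
  row1 <- mean_row
  row1[1, j] <- m$center[j] + m$scale[j]
  expect_equal(unname(score_patterns(m, row1)[1, ]),
               unname(m$loadings[j, ]), tolerance = 1e-10)
  # training rows re-score identically
  expect_equal(score_patterns(m, x[1:5, , drop = FALSE]),
               score_patterns(m, x)[1:5, , drop = FALSE])
  expect_error(score_patterns(m, x[, -1]), "lacks item")
})

test_that("degenerate pattern inputs are rejected", {
  x <- make_freq_matrix(n = 50)
  expect_error(fit_patterns(x, k = ncol(x) + 1), "between 1")
  x2 <- x; x2[, 2] <- 1
  expect_error(fit_patterns(x2, k = 2), "all-constant")
  x3 <- x; x3[1, 1] <- NA
  expect_error(fit_patterns(x3, k = 2), "complete")
})

test_that("pattern models survive a JSON round trip", {
  x <- make_freq_matrix(n = 80)
  m <- fit_patterns(x, k = 4)
  m$names <- c("health conscious", "traditional", "processed", "confectionery")
  path <- tempfile(fileext = ".json")
  save_pattern_model(m, path)
  m2 <- load_pattern_model(path)
  expect_equal(m2$loadings, m$loadings, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(score_patterns(m2, x), score_patterns(m, x), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("AOAC fibre is exactly 1.33 x NSP", {
  expect_equal(aoac_from_nsp(10), 13.3)
  expect_equal(aoac_from_nsp(0), 0)
  expect_equal(aoac_from_nsp(14.9), 19.817)
  expect_error(aoac_from_nsp(-1), ">= 0")
  expect_equal(aoac_from_nsp(c(2, 4)), 2 * aoac_from_nsp(c(1, 2)))
})

test_that("energy standardisation matches the conversion-factor arithmetic", {
  d <- to_daily(plausible_weekly())
  pc <- energy_standardise(d, "percent")
  expect_equal(unname(pc["protein"]), 69.3 * 17 / 7230 * 100, tolerance = 1e-12)
  expect_equal(unname(pc["fat"]), 71 * 37 / 7230 * 100, tolerance = 1e-12)
  dens <- energy_standardise(d, "density")
  expect_equal(unname(dens["iron_mg_per_mj"]), 10.2 / 7.23, tolerance = 1e-12)
  # zero macronutrient -> zero share; zero energy -> error
  zero_fat <- unclass(d); zero_fat["fat_g"] <- 0
  expect_equal(unname(energy_standardise(nutrient_vector(zero_fat, "daily"),
                                         "percent")["fat"]), 0)
  zeroed <- unclass(d); zeroed[] <- 0
  expect_error(energy_standardise(nutrient_vector(zeroed, "daily")), "energy")
})

test_that("misreporter flags classify the reported/predicted ratio", {
  # 60 kg: predicted = (0.062*60 + 2.036) * 1.4 = 8.0584 MJ/day
  pred <- (0.062 * 60 + 2.036) * 1.4
  f <- flag_misreporters(c(3, pred, 20), c(60, 60, 60))
  expect_equal(f$class, c("under", "plausible", "over"))
  expect_equal(f$predicted_mj, rep((0.062 * 60 + 2.036) * 1.4, 3))
  expect_equal(f$ratio[2], 1, tolerance = 1e-12)
  expect_message(f2 <- flag_misreporters(5, NA_real_), "without a weight")
  expect_equal(f2$class, "plausible")
  expect_error(flag_misreporters(5, -10), "> 0")
})
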
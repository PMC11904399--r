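#' Fish n-3, EPA and DHA intake from the three seafood questions
#'
#' Closed form: for each fish class (white, oily, shellfish), weekly grams =
#' recoded times/week x the per-portion constant (n-3: 0.32, 0.89 and 0.35 g
#' per portion of white fish, oily fish and shellfish respectively); daily
#' values divide by 7. The EPA and DHA per-portion constants are package
#' defaults (the split is not printed with the n-3 constants) chosen so each
#' class keeps DHA > EPA and EPA + DHA <= n-3; they live in the config.
#'
#' @param freq_white,freq_oily,freq_shell Recoded consumption frequencies in
#'   times per week (non-negative).
#' @param config Constants from [ffq_config()].
#' @param basis "daily" (default) or "weekly".
#' @return Named numeric vector \code{c(n3, epa, dha)} in g on the requested
#'   basis.
#' @export
fish_fatty_acids <- function(freq_white, freq_oily, freq_shell,
                             config = default_constants(),
                             basis = c("daily", "weekly")) {
  basis <- match.arg(basis)
  f <- c(white = freq_white, oily = freq_oily, shellfish = freq_shell)
  if (any(!is.finite(f)) || any(f < 0)) {
    stop("fish frequencies must be finite and >= 0")
  }
  fc <- config$fish
  per <- function(const) sum(f * unlist(const[names(f)]))
  out <- c(n3 = per(fc$n3_per_portion_g),
           epa = per(fc$epa_per_portion_g),
           dha = per(fc$dha_per_portion_g))
  if (basis == "daily") out <- out / 7
  out
}

#' Weekly caffeine intake from tea, coffee and cola counts
#'
#' Weekly mg = 7 x (caffeinated cups of tea x 27 + caffeinated cups of
#' coffee x 57 + caffeinated cola drinks x 20); decaffeinated drinks
#' contribute nothing.
#'
#' @param cups_tea,cups_coffee,colas Caffeinated drink counts per day
#'   (decaffeinated counts are simply not passed, or zeroed via the flags).
#' @param decaf_tea,decaf_coffee,decaf_cola When TRUE the corresponding
#'   count is treated as decaffeinated and contributes 0.
#' @param config Constants from [ffq_config()].
#' @return Caffeine in mg per week.
#' @export
caffeine_weekly <- function(cups_tea = 0, cups_coffee = 0, colas = 0,
                            decaf_tea = FALSE, decaf_coffee = FALSE,
                            decaf_cola = FALSE,
                            config = default_constants()) {
  counts <- c(cups_tea, cups_coffee, colas)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("drink counts must be finite and >= 0")
  }
  cc <- config$caffeine
  7 * ((!decaf_tea) * cups_tea * cc$mg_per_cup_tea +
         (!decaf_coffee) * cups_coffee * cc$mg_per_cup_coffee +
         (!decaf_cola) * colas * cc$mg_per_cola)
}

#' Average weekday/weekend drink counts to a daily count
#'
#' The earlier-pregnancy questionnaires record drinks separately for
#' weekdays and weekend days; the working daily count is the
#' calendar-weighted mean (5 x weekday + 2 x weekend) / 7.
#'
#' @param weekday,weekend Counts per day.
#' @return Averaged count per day.
#' @export
average_drink_counts <- function(weekday, weekend) {
  (5 * weekday + 2 * weekend) / 7
}
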
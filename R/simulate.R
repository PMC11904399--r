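#' Default latent dietary-pattern loadings for the simulator
#'
#' Five latent patterns over the 43 weekly items, shaped after the verbal
#' structure of the cohort's published patterns: a health-conscious axis
#' (salad, fruit, rice, pasta, cereals, fish, pulses, juices, poultry), a
#' traditional axis (vegetables, red meat, poultry, potatoes), a processed
#' axis (high-fat processed foods), a confectionery axis (sugary snacks) and
#' a vegetarian axis (meat substitutes, pulses, nuts; negative on red meat
#' and poultry). Magnitudes are simulation inputs, not estimates.
#'
#' @return 43 x 5 numeric matrix, rows named by variable code, columns by
#'   pattern label.
#' @export
default_pattern_loadings <- function() {
  codes <- weekly_codes(ffq_schema())
  L <- matrix(0, length(codes), 5,
              dimnames = list(codes, c("health_conscious", "traditional",
                                       "processed", "confectionery",
                                       "vegetarian")))
  set_load <- function(col, codes_pos, v = 0.6) L[codes_pos, col] <<- v
  set_load("health_conscious", c("c228", "c229", "c217", "c218", "c233",
                                 "c234", "c205", "c206", "c208", "c231",
                                 "c230", "c225", "c203"))
  set_load("traditional", c("c223", "c224", "c225", "c226", "c227", "c202",
                            "c203", "c215", "c216", "c204"))
  set_load("processed", c("c200", "c201", "c210", "c211", "c219", "c220",
                          "c222"))
  set_load("confectionery", c("c232", "c236", "c238", "c239", "c245", "c246"))
  set_load("vegetarian", c("c240", "c241", "c242", "c243", "c244"))
  set_load("vegetarian", c("c200", "c202", "c203"), -0.6)
  L
}

# per-item baseline (softplus-input scale) giving plausible mean frequencies:
# staples around twice a week, rarer foods well under once a week
default_item_means <- function() {
  codes <- weekly_codes(ffq_schema())
  mu <- stats::setNames(rep(0.5, length(codes)), codes)
  staples <- c("c202", "c203", "c209", "c216", "c226", "c228", "c229",
               "c235", "c238", "c245")
  occasional <- c("c204", "c207", "c242", "c243", "c244", "c241", "c230")
  mu[staples] <- 2
  mu[occasional] <- -2
  mu
}

#' Build a synthetic-cohort configuration
#'
#' Defaults emulate the demographics of the real 32-week cohort's FFQ
#' completers (education A level or degree 35.4%, smoking 19.8%, owned or
#' mortgaged housing 75.7%, age 28.6 (4.8) years, pre-pregnancy BMI 22.9
#' (3.8) kg/m^2) and a latent five-pattern diet structure. Missingness and
#' injected misreporting are per-item/per-participant Bernoulli processes.
#'
#' @param n Cohort size.
#' @param loadings Latent loading matrix (items x k), default
#'   [default_pattern_loadings()].
#' @param score_sd Latent score SDs (recycled over components).
#' @param item_means Baseline per-item values on the softplus-input scale.
#' @param noise_sd SD of the per-item frequency noise.
#' @param missingness Per-cell probability that a weekly item is unanswered.
#' @param misreport_fraction Fraction of participants whose reported weekly
#'   frequencies are scaled by \code{misreport_factor} (0 disables).
#' @param misreport_factor Reporting scale factor for injected misreporters.
#' @param bin_edges Cut points (times/week) mapping a true frequency to the
#'   five response categories; chosen so category midpoints track the recode
#'   weights.
#' @param demographics List of proportions and moments (see defaults).
#' @return Validated config list of class \code{cohort_config}.
#' @export
cohort_config <- function(n = 1000,
                          loadings = default_pattern_loadings(),
                          score_sd = 1,
                          item_means = default_item_means(),
                          noise_sd = 0.5,
                          missingness = 0.05,
                          misreport_fraction = 0,
                          misreport_factor = 0.5,
                          bin_edges = c(0.25, 1.25, 3.5, 7.5),
                          demographics = list(
                            p_edu_alevel = 0.354,
                            p_smoking = 0.198,
                            p_housing_owned = 0.757,
                            age_mean = 28.6, age_sd = 4.8,
                            bmi_mean = 22.9, bmi_sd = 3.8,
                            height_mean_m = 1.63, height_sd_m = 0.06)) {
  stopifnot(n >= 1, is.matrix(loadings), all(is.finite(loadings)),
            length(bin_edges) == 4, !is.unsorted(bin_edges))
  props <- c(missingness, misreport_fraction, demographics$p_edu_alevel,
             demographics$p_smoking, demographics$p_housing_owned)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  if (misreport_factor < 0) stop("misreport_factor must be >= 0")
  if (!setequal(rownames(loadings), names(item_means))) {
    stop("loadings rows and item_means must cover the same item codes")
  }
  structure(list(n = as.integer(n), loadings = loadings,
                 score_sd = rep_len(score_sd, ncol(loadings)),
                 item_means = item_means, noise_sd = noise_sd,
                 missingness = missingness,
                 misreport_fraction = misreport_fraction,
                 misreport_factor = misreport_factor,
                 bin_edges = bin_edges, demographics = demographics),
            class = "cohort_config")
}

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  ifelse(x > 30, x, log1p(exp(x)))
}

bin_frequency <- function(freq, edges) {
  labels <- weekly5_labels()
  labels[findInterval(freq, edges) + 1]
}

#' Generate a synthetic questionnaire cohort with known latent truth
#'
#' True times/week for item j of participant i is
#' softplus(mu_j + sum_k score_ik loading_jk + noise); the recorded response
#' is the five-category bin containing the (possibly misreport-scaled) true
#' frequency. Daily-basics answers (bread, milk, fats, sugar, drinks, diet
#' behaviour) are drawn from fixed categorical distributions. Everything is
#' reproducible from \code{seed}.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed driving all randomness.
#' @param portions,composition Tables used to record the latent true weekly
#'   energy in the truth object (same tables the derivation will use).
#' @param truth_energy Record the latent true weekly energy per participant
#'   (a per-participant pass over the portion tables; disable when only the
#'   responses or demographics are needed).
#' @return List with \code{responses} (an \code{ffq_responses}) and
#'   \code{truth} (list: scores, true_freq, reported_freq, misreporter,
#'   misreport_factor, demographics incl. weight_kg, true_energy_kj_week).
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1,
                            portions = load_portion_table(),
                            composition = load_composition(),
                            truth_energy = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  n <- config$n
  L <- config$loadings
  codes <- rownames(L)
  k <- ncol(L)

  dg <- config$demographics
  demo <- data.frame(
    participant_id = sprintf("P%05d", seq_len(n)),
    edu_alevel = stats::rbinom(n, 1, dg$p_edu_alevel) == 1,
    smoker = stats::rbinom(n, 1, dg$p_smoking) == 1,
    housing_owned = stats::rbinom(n, 1, dg$p_housing_owned) == 1,
    age = stats::rnorm(n, dg$age_mean, dg$age_sd),
    bmi = pmax(15, stats::rnorm(n, dg$bmi_mean, dg$bmi_sd)),
    height_m = pmax(1.4, stats::rnorm(n, dg$height_mean_m, dg$height_sd_m)),
    stringsAsFactors = FALSE)
  demo$weight_kg <- demo$bmi * demo$height_m^2

  scores <- matrix(stats::rnorm(n * k), n, k) %*% diag(config$score_sd, k)
  colnames(scores) <- colnames(L)
  eta <- matrix(config$item_means[codes], n, length(codes), byrow = TRUE) +
    scores %*% t(L) +
    matrix(stats::rnorm(n * length(codes), 0, config$noise_sd), n)
  true_freq <- softplus(eta)
  colnames(true_freq) <- codes

  misreporter <- stats::runif(n) < config$misreport_fraction
  factor_i <- ifelse(misreporter, config$misreport_factor, 1)
  reported_freq <- true_freq * factor_i

  answers <- matrix(bin_frequency(reported_freq, config$bin_edges),
                    n, length(codes), dimnames = list(NULL, codes))
  if (config$missingness > 0) {
    drop <- matrix(stats::runif(n * length(codes)) < config$missingness,
                   n, length(codes))
    answers[drop] <- NA_character_
  }

  df <- data.frame(participant_id = demo$participant_id, answers,
                   check.names = FALSE, stringsAsFactors = FALSE)

  pick <- function(labels, probs) labels[sample.int(length(labels), n,
                                                    replace = TRUE, prob = probs)]
  yn <- function(p) ifelse(stats::runif(n) < p, "yes", "no")
  usn <- c("yes usually", "yes sometimes", "no not at all")

  df$c221 <- pick(c("yes, all of it", "yes, some of it", "no", "never eat meat"),
                  c(0.2, 0.35, 0.4, 0.05))
  df$c247 <- pick(c("always", "sometimes", "not at all", "don't drink soft drinks"),
                  c(0.25, 0.3, 0.35, 0.1))
  df$c250 <- pick(c("less than 1", "1-2", "3-4", "5 or more"),
                  c(0.15, 0.45, 0.3, 0.1))
  df$c251 <- pick(c("never or rarely", "1-2", "3-4", "5-9", "10 or more"),
                  c(0.3, 0.4, 0.2, 0.08, 0.02))
  df$c252 <- yn(0.6); df$c253 <- yn(0.25); df$c254 <- yn(0.25)
  df$c255 <- yn(0.05); df$c256 <- yn(0.03)
  df$c260 <- yn(0.35); df$c261 <- yn(0.45); df$c262 <- yn(0.2)
  df$c263 <- yn(0.2); df$c264 <- yn(0.05); df$c265 <- yn(0.05)
  df$c266 <- yn(0.15); df$c267 <- yn(0.2); df$c268 <- yn(0.05)
  df$c269 <- yn(0.05); df$c270 <- yn(0.5); df$c271 <- yn(0.3)
  # misreporters under-state quantities across the questionnaire: counts
  # scale by the same factor as the weekly frequencies (categorical ticks
  # cannot be scaled and stay as answered)
  cnt <- function(lambda) as.character(round(stats::rpois(n, lambda) * factor_i, 2))
  df$c275 <- cnt(2)
  df$c276 <- pick(usn, c(0.45, 0.15, 0.4))
  df$c277 <- pick(usn, c(0.35, 0.2, 0.45))
  df$c278 <- pick(usn, c(0.15, 0.15, 0.7))
  df$c279 <- pick(usn, c(0.05, 0.05, 0.9))
  df$c280 <- pick(usn, c(0.03, 0.07, 0.9))
  df$c281 <- pick(usn, c(0.01, 0.02, 0.97))
  df$c282 <- pick(usn, c(0.02, 0.03, 0.95))
  df$c283 <- pick(usn, c(0.01, 0.02, 0.97))
  df$c284 <- pick(usn, c(0.75, 0.1, 0.15))
  df$c285 <- pick(usn, c(0.6, 0.15, 0.25))
  df$c286 <- pick(usn, c(0.6, 0.2, 0.2))
  df$c287 <- pick(usn, c(0.2, 0.4, 0.4))
  df$c288 <- pick(usn, c(0.25, 0.3, 0.45))
  df$c289 <- pick(usn, c(0.2, 0.35, 0.45))
  df$c300 <- cnt(2.5)
  df$c301 <- cnt(0.3)
  df$c302 <- cnt(0.8)
  df$c304 <- cnt(1.5)
  df$c305 <- cnt(0.3)
  df$c306 <- cnt(0.8)
  df$c310 <- cnt(0.4)
  df$c311 <- cnt(0.2)

  responses <- ffq_responses(df)

  # latent true weekly energy: continuous frequencies x per-question energy,
  # plus the participant's actual basics contributions (no binning, no
  # missingness)
  true_energy <- rep(NA_real_, n)
  if (truth_energy) {
  profiles <- build_profiles(portions, composition)
  schema <- ffq_schema()
  qmap <- stats::setNames(schema$items$question_id, schema$items$code)
  energy_of <- function(code, behaviour) {
    prof <- profiles[[qmap[[code]]]]
    if (is.null(prof)) return(0)
    if (is.list(prof)) prof <- prof[[behaviour_variant(behaviour)]]
    prof[["energy_kj"]]
  }
  basics_df <- df
  basics_df[codes] <- NA_character_
  basics_resp <- ffq_responses(basics_df)
  for (i in seq_len(n)) {
    row <- response_row(basics_resp, i)
    base <- weekly_nutrients(row, portions, composition, schema = schema,
                             profiles = profiles)
    eq <- vapply(codes, energy_of, numeric(1), behaviour = df$c221[i])
    true_energy[i] <- unclass(base)[["energy_kj"]] + sum(true_freq[i, ] * eq)
  }
  }

  truth <- list(participant_id = demo$participant_id, scores = scores,
                true_freq = true_freq, reported_freq = reported_freq,
                misreporter = misreporter, misreport_factor = factor_i,
                demographics = demo, true_energy_kj_week = true_energy,
                loadings = L)
  list(responses = responses, truth = truth)
}

#' Recoded frequency matrix of a response cohort
#'
#' @param responses An \code{ffq_responses}.
#' @param schema The schema (weekly items define the columns).
#' @param config Constants (frequency weights).
#' @return Numeric matrix participants x weekly items (times/week).
#' @export
frequency_matrix <- function(responses, schema = ffq_schema(),
                             config = default_constants()) {
  codes <- weekly_codes(schema)
  df <- as.data.frame(responses)
  out <- sapply(codes, function(code) {
    col <- if (code %in% names(df)) df[[code]] else rep(NA_character_, nrow(df))
    recode_frequency(col, config$frequency_weights)
  })
  rownames(out) <- df$participant_id
  out
}

#' Recovery metrics for a synthetic cohort
#'
#' Compares the derivation and pattern fit against the generator's latent
#' truth: correlation of true vs derived weekly energy, per-pattern loading
#' recovery (each true loading vector matched to the fitted component of
#' maximal absolute correlation), and the misreporter-flag confusion matrix.
#'
#' @param truth The \code{truth} element of [generate_cohort()].
#' @param derived Result of [derive_nutrients()] on the same cohort.
#' @param model Optional [fit_patterns()] model to score against the truth.
#' @param flags Optional [flag_misreporters()] result (same participant
#'   order as the truth).
#' @return List with \code{energy_correlation}, \code{loading_recovery}
#'   (matched |r| per true pattern), \code{misreport_confusion} (table) as
#'   available.
#' @export
recovery_report <- function(truth, derived, model = NULL, flags = NULL) {
  ids <- rownames(derived$weekly)
  if (!identical(ids, truth$participant_id)) {
    stop("participant ids of truth and derived output do not match")
  }
  out <- list()
  out$energy_correlation <- stats::cor(truth$true_energy_kj_week,
                                       derived$weekly[, "energy_kj"])
  if (!is.null(model)) {
    common <- intersect(rownames(truth$loadings), rownames(model$loadings))
    r <- abs(stats::cor(truth$loadings[common, , drop = FALSE],
                        model$loadings[common, , drop = FALSE]))
    out$loading_recovery <- apply(r, 1, max)
    out$loading_match <- apply(r, 1, which.max)
  }
  if (!is.null(flags)) {
    out$misreport_confusion <- table(truth = truth$misreporter,
                                     flagged_under = flags$class == "under")
  }
  out
}
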
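#' Fit dietary patterns by principal components analysis
#'
#' Columns (recoded item frequencies, times/week; alcohol items are not part
#' of the schema) are standardised to mean 0, SD 1; the first \code{k}
#' principal axes are extracted and varimax-rotated (rotation configurable).
#' The fitted loadings are an orthonormal basis of the retained subspace, so
#' rotation preserves the subspace's total explained variance. Sign
#' convention: each component's largest-magnitude loading is positive, which
#' makes the fit deterministic for a given input.
#'
#' @param x Numeric matrix or data frame, participants x items, with item
#'   column names. No missing values; no all-constant column.
#' @param k Number of components to retain (5 in the source derivation).
#' @param rotate "varimax" (default) or "none".
#' @return Object of class \code{pattern_model}: list with \code{k},
#'   \code{items}, \code{center}, \code{scale}, \code{loadings} (items x k),
#'   \code{rotate}, \code{explained} (proportion of total variance retained)
#'   and \code{names} (component labels, settable post hoc).
#' @export
fit_patterns <- function(x, k, rotate = c("varimax", "none")) {
  rotate <- match.arg(rotate)
  x <- as.matrix(x)
  if (is.null(colnames(x))) stop("pattern input needs item column names")
  if (anyNA(x)) stop("pattern input must be complete")
  if (k < 1 || k > ncol(x)) stop("k must be between 1 and the item count")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("all-constant item column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  }
  pca <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  load <- pca$rotation[, seq_len(k), drop = FALSE]
  if (rotate == "varimax" && k > 1) {
    load <- unclass(stats::varimax(load)$loadings)
  }
  # sign convention: largest-|loading| entry positive per component
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  colnames(load) <- paste0("PC", seq_len(k))
  explained <- sum(pca$sdev[seq_len(k)]^2) / sum(pca$sdev^2)
  structure(list(k = k, items = colnames(x), center = pca$center,
                 scale = pca$scale, loadings = load, rotate = rotate,
                 explained = explained, names = NULL),
            class = "pattern_model")
}

#' Score participants against a fitted pattern model
#'
#' Pure standardised projection: Z = (x - center) / scale, scores = Z L.
#' A row at the training mean scores zero on every component; a row one
#' training SD above the mean on a single item scores that item's loading
#' row.
#'
#' @param model A [fit_patterns()] model.
#' @param x Matrix or data frame with exactly the model's item columns; no
#'   missing values (frequencies are recoded, with missing handled, upstream).
#' @return Numeric matrix, participants x k.
#' @export
score_patterns <- function(model, x) {
  stopifnot(inherits(model, "pattern_model"))
  x <- as.matrix(x)
  if (is.null(colnames(x)) || !all(model$items %in% colnames(x))) {
    missing <- setdiff(model$items, colnames(x))
    stop("scoring input lacks item(s): ", paste(missing, collapse = ", "))
  }
  x <- x[, model$items, drop = FALSE]
  if (anyNA(x)) stop("scoring input must be complete")
  z <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  s <- z %*% model$loadings
  if (!is.null(model$names)) colnames(s) <- model$names
  s
}

#' @export
print.pattern_model <- function(x, ...) {
  cat("Dietary pattern model: ", x$k, " components over ", length(x$items),
      " items (", x$rotate, " rotation, ",
      round(100 * x$explained, 1), "% variance retained)\n", sep = "")
  invisible(x)
}

#' Persist / restore a pattern model as JSON
#'
#' @param model A \code{pattern_model}.
#' @param path JSON file path.
#' @return \code{save_pattern_model}: the path, invisibly;
#'   \code{load_pattern_model}: the restored model.
#' @export
save_pattern_model <- function(model, path) {
  stopifnot(inherits(model, "pattern_model"))
  obj <- list(k = model$k, items = model$items,
              center = as.list(model$center), scale = as.list(model$scale),
              loadings = apply(model$loadings, 2, identity, simplify = FALSE),
              rotate = model$rotate, explained = model$explained,
              names = model$names)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_pattern_model
#' @export
load_pattern_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  load <- do.call(cbind, obj$loadings)
  rownames(load) <- obj$items
  structure(list(k = obj$k, items = obj$items,
                 center = stats::setNames(unlist(obj$center), obj$items),
                 scale = stats::setNames(unlist(obj$scale), obj$items),
                 loadings = load, rotate = obj$rotate,
                 explained = obj$explained,
                 names = if (length(obj$names)) obj$names else NULL),
            class = "pattern_model")
}

#' AOAC fibre from NSP fibre
#'
#' AOAC (g) = NSP (g) x 1.33 exactly (the enzymatic-gravimetric fibre
#' definition derived from the non-starch polysaccharide value).
#'
#' @param nsp_g NSP fibre in g (non-negative).
#' @param factor Conversion factor, default 1.33.
#' @return AOAC fibre in g.
#' @export
aoac_from_nsp <- function(nsp_g, factor = default_constants()$aoac_factor) {
  if (any(!is.finite(nsp_g)) || any(nsp_g < 0)) stop("nsp must be finite and >= 0")
  nsp_g * factor
}

#' Standardise nutrient intakes for energy
#'
#' Mode "percent": macronutrient energy share, g x energy-conversion factor
#' (protein 17, fat 37, carbohydrate 16 kJ/g) / energy kJ x 100. Mode
#' "density": every non-energy slot per MJ of energy.
#'
#' @param v A daily \code{nutrient_vector} with energy > 0.
#' @param mode "percent" or "density".
#' @param config Constants from [ffq_config()].
#' @return Named numeric vector: percent-energy shares of protein, fat and
#'   carbohydrate, or nutrient densities per MJ.
#' @export
energy_standardise <- function(v, mode = c("percent", "density"),
                               config = default_constants()) {
  mode <- match.arg(mode)
  stopifnot(inherits(v, "nutrient_vector"))
  vals <- unclass(v)
  if (vals[["energy_kj"]] <= 0) stop("energy must be > 0 to standardise")
  if (mode == "percent") {
    f <- config$energy_conversion_kj_per_g
    shares <- c(protein = vals[["protein_g"]] * f$protein,
                fat = vals[["fat_g"]] * f$fat,
                carbohydrate = vals[["carbohydrate_g"]] * f$carbohydrate)
    shares / vals[["energy_kj"]] * 100
  } else {
    mj <- vals[["energy_kj"]] / 1000
    out <- vals[setdiff(names(vals), "energy_kj")] / mj
    stats::setNames(out, paste0(setdiff(names(vals), "energy_kj"), "_per_mj"))
  }
}

#' Flag likely energy-intake misreporters
#'
#' Predicted energy requirement = basal metabolic rate x physical activity
#' level, with BMR from the Schofield equation for women aged 18-29
#' (0.062 x weight kg + 2.036 MJ/day). The reported/predicted ratio is
#' classified against Goldberg-style bounds (defaults 0.54 and 2.0):
#' below the lower bound is under-reporting, above the upper over-reporting.
#' A missing weight cannot be screened and is classed plausible with a
#' caveat message.
#'
#' @param energy_mj_day Reported daily energy in MJ (vector).
#' @param weight_kg Pre-pregnancy body weight in kg (vector, NA allowed).
#' @param pal Physical activity level; default from config (1.4).
#' @param config Constants from [ffq_config()].
#' @return Data frame: predicted_mj, ratio, class ("under", "plausible",
#'   "over") with the bounds attached as attributes.
#' @export
flag_misreporters <- function(energy_mj_day, weight_kg,
                              pal = NULL, config = default_constants()) {
  mc <- config$misreporting
  if (is.null(pal)) pal <- mc$pal
  stopifnot(length(energy_mj_day) == length(weight_kg))
  if (any(weight_kg[!is.na(weight_kg)] <= 0)) stop("weight must be > 0")
  bmr <- mc$schofield$weight_coef_mj * weight_kg + mc$schofield$intercept_mj
  predicted <- bmr * pal
  ratio <- energy_mj_day / predicted
  cls <- ifelse(ratio < mc$ratio_lower, "under",
                ifelse(ratio > mc$ratio_upper, "over", "plausible"))
  if (anyNA(weight_kg)) {
    message(sum(is.na(weight_kg)),
            " participant(s) without a weight: classed plausible unscreened")
    cls[is.na(weight_kg)] <- "plausible"
  }
  structure(data.frame(predicted_mj = predicted, ratio = ratio, class = cls,
                       stringsAsFactors = FALSE),
            bounds = c(lower = mc$ratio_lower, upper = mc$ratio_upper),
            pal = pal)
}
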
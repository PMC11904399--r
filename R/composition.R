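#' Load a food-composition table
#'
#' Reads nutrient densities per 100 g by food code from CSV. The file must
#' have \code{food_code} and \code{description} columns followed by one
#' column per composition slot named \code{<slot>_per100g} (e.g.
#' \code{energy_kj_per100g}); see [composition_slots()]. A slot column absent
#' from the file is filled with zero and logged as a gap, so the engine stays
#' total; negative densities are an error.
#'
#' The package ships a fully synthetic table
#' (\code{inst/extdata/composition_synthetic.csv}) with plausible densities
#' for every packaged food code; a real licensed table can be supplied in the
#' same format.
#'
#' @param path CSV path; default the packaged synthetic table.
#' @return An object of class \code{composition_table}: list with
#'   \code{codes}, \code{descriptions} and a numeric \code{densities} matrix
#'   (codes x composition slots, per 100 g).
#' @export
load_composition <- function(path = ffqkit_extdata("composition_synthetic.csv")) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  stopifnot(all(c("food_code", "description") %in% names(df)))
  slots <- composition_slots()
  wanted <- paste0(slots, "_per100g")
  missing_cols <- setdiff(wanted, names(df))
  if (length(missing_cols)) {
    message("composition table gap: ", length(missing_cols),
            " slot column(s) absent, filled with zero: ",
            paste(sub("_per100g$", "", missing_cols), collapse = ", "))
    for (m in missing_cols) df[[m]] <- 0
  }
  codes <- as.character(df$food_code)
  if (anyDuplicated(codes)) stop("duplicate food_code in composition table")
  dens <- as.matrix(df[, wanted, drop = FALSE])
  mode(dens) <- "numeric"
  if (anyNA(dens)) stop("non-numeric or missing density in composition table")
  if (any(dens < 0)) stop("negative density in composition table")
  colnames(dens) <- slots
  rownames(dens) <- codes
  structure(list(codes = codes, descriptions = as.character(df$description),
                 densities = dens),
            class = "composition_table")
}

#' Load the portion-assignment table
#'
#' Reads the per-question food/portion assignments: for each question a
#' default component list of (food code, grams), optional nutrient-specific
#' alternates (tagged \code{vitaminE}, \code{folate}, \code{retinol},
#' \code{carotene}, \code{vitaminC}, \code{zinc}, \code{pyridoxine},
#' \code{niacin}, \code{fattyAcids}, \code{totalFatEnergy}) and, for the meat
#' questions, the fat-on-meat behaviour variants (\code{fat_all},
#' \code{fat_some}, \code{fat_none}).
#'
#' @param path CSV with columns question_id, variant, food_code, description,
#'   grams; default the packaged transcription.
#' @return Object of class \code{portion_table}: the validated data frame.
#' @export
load_portion_table <- function(path = ffqkit_extdata("portion_table.csv")) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                        colClasses = c(question_id = "character",
                                       variant = "character",
                                       food_code = "character",
                                       description = "character",
                                       grams = "numeric"))
  need <- c("question_id", "variant", "food_code", "description", "grams")
  stopifnot(all(need %in% names(df)))
  bad_tag <- setdiff(unique(df$variant), variant_tags())
  if (length(bad_tag)) {
    stop("unrecognised portion-variant tag(s): ", paste(bad_tag, collapse = ", "))
  }
  if (any(!is.finite(df$grams)) || any(df$grams <= 0)) {
    stop("portion grams must be finite and > 0")
  }
  key <- paste(df$question_id, df$variant, df$food_code)
  if (anyDuplicated(key)) {
    stop("duplicate portion component: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  # behaviour-variant questions carry fat_* blocks instead of a default
  has_default <- tapply(df$variant, df$question_id,
                        function(v) any(v == "default") ||
                          all(v %in% c("fat_all", "fat_some", "fat_none")))
  if (any(!has_default)) {
    stop("portion table question(s) without a default variant: ",
         paste(names(has_default)[!has_default], collapse = ", "))
  }
  structure(df, class = c("portion_table", "data.frame"))
}

# variant tag whose alternate list serves `slot` for `question`, or NULL
variant_for_slot <- function(portions, question, slot) {
  tags <- unique(portions$variant[portions$question_id == question])
  map <- variant_slot_map()
  for (tag in intersect(tags, names(map))) {
    if (slot %in% map[[tag]]) return(tag)
  }
  NULL
}

#' Portion component list for a question, nutrient and behaviour
#'
#' Resolves which (food code, grams) list stands in for one consumption
#' occasion of a question: the nutrient-specific alternate if one exists for
#' the requested slot, else the default; for the meat questions the
#' fat-on-meat behaviour answer selects the all/some/none variant ("never eat
#' meat" resolves to the lean-only list; a missing behaviour answer to the
#' lean-and-fat list).
#'
#' @param portions A [load_portion_table()] result.
#' @param question Question id (e.g. "c3a").
#' @param slot Nutrient slot name, or NULL for the default list.
#' @param behaviour Raw fat-on-meat answer (variable c221), only consulted
#'   for questions carrying behaviour variants.
#' @return Data frame with food_code, description, grams (possibly 0 rows
#'   only for questions absent from the table, which is an error).
#' @export
portion_for <- function(portions, question, slot = NULL, behaviour = NULL) {
  rows <- portions[portions$question_id == question, , drop = FALSE]
  if (!nrow(rows)) stop("unknown question in portion table: ", question)
  tags <- unique(rows$variant)
  if (any(tags %in% c("fat_all", "fat_some", "fat_none"))) {
    tag <- behaviour_variant(behaviour)
  } else {
    tag <- NULL
    if (!is.null(slot)) tag <- variant_for_slot(portions, question, slot)
    if (is.null(tag)) tag <- "default"
  }
  out <- rows[rows$variant == tag, c("food_code", "description", "grams")]
  if (!nrow(out)) stop("question ", question, " has no '", tag, "' variant")
  out
}

behaviour_variant <- function(behaviour) {
  if (is.null(behaviour) || is.na(behaviour)) return("fat_all")
  switch(normalise_label(behaviour),
         "yes, all of it"  = "fat_all",
         "yes, some of it" = "fat_some",
         "no"              = "fat_none",
         "never eat meat"  = "fat_none",
         stop("unrecognised fat-on-meat answer: ", behaviour))
}

#' Nutrient content of a portion component list
#'
#' Pure portion-weighted composition sum: for each slot,
#' \code{sum(grams/100 * density(code, slot))}.
#'
#' @param components Data frame with food_code and grams (e.g. from
#'   [portion_for()]), or a 0-row frame for an all-zero result.
#' @param composition A [load_composition()] table.
#' @return Named numeric vector over [composition_slots()].
#' @export
portion_nutrients <- function(components, composition) {
  slots <- composition_slots()
  if (!nrow(components)) {
    return(stats::setNames(numeric(length(slots)), slots))
  }
  codes <- as.character(components$food_code)
  unknown <- setdiff(codes, composition$codes)
  if (length(unknown)) {
    stop("food code(s) missing from composition table: ",
         paste(unknown, collapse = ", "))
  }
  w <- components$grams / 100
  dens <- composition$densities[codes, , drop = FALSE]
  stats::setNames(as.numeric(crossprod(dens, w)), slots)
}

#' Load the fish subtype mixes
#'
#' The white / other (oily) / shellfish classes are each coded as a gram mix
#' of typical British subtypes; the mixes document what one portion of each
#' seafood question represents.
#'
#' @param path CSV with columns fish_class, description, grams; default the
#'   packaged transcription.
#' @return Data frame of class \code{fish_mix}.
#' @export
load_fish_mix <- function(path = ffqkit_extdata("fish_mix.csv")) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  stopifnot(all(c("fish_class", "description", "grams") %in% names(df)))
  if (any(df$grams <= 0)) stop("fish mix grams must be > 0")
  structure(df, class = c("fish_mix", "data.frame"))
}

#' Total portion weight of a fish class
#'
#' @param mix A [load_fish_mix()] table.
#' @param fish_class One of "white", "oily", "shellfish".
#' @return Total grams (0 for a class with no components).
#' @export
total_portion_grams <- function(mix, fish_class) {
  sum(mix$grams[mix$fish_class == fish_class])
}

# path helper for packaged fixtures
ffqkit_extdata <- function(file) {
  path <- system.file("extdata", file, package = "ffqkit")
  if (path == "") {
    # during in-source testing before installation
    path <- file.path("inst", "extdata", file)
  }
  if (!file.exists(path)) stop("packaged fixture not found: ", file)
  path
}
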
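#' Write derived nutrient vectors to delimited text
#'
#' Writes one row per kept participant with a deterministic column order
#' (participant_id, basis, then [nutrient_slots()]); participants carrying
#' exclusion flags go to a companion exclusion log (same path with an
#' \code{_exclusions.csv} suffix) naming the violated rules, not to the main
#' file.
#'
#' @param records Named list of \code{nutrient_vector}s (names are
#'   participant ids), all on the same basis.
#' @param path Output CSV path.
#' @param exclusions Optional data frame (participant_id, rules) of flagged
#'   participants, e.g. from [derive_nutrients()].
#' @return Invisibly, a list with the main and exclusion-log paths.
#' @export
write_nutrients <- function(records, path, exclusions = NULL) {
  stopifnot(is.list(records), length(names(records)) == length(records))
  if (length(records)) {
    ok <- vapply(records, inherits, logical(1), "nutrient_vector")
    if (!all(ok)) stop("records must be nutrient_vector objects")
    bases <- vapply(records, attr, character(1), "basis")
    if (length(unique(bases)) > 1) stop("records mix weekly and daily bases")
  }
  excl_path <- sub("(\\.[^.]+)?$", "_exclusions.csv", path)
  flagged <- if (is.null(exclusions)) character(0) else exclusions$participant_id
  keep <- setdiff(names(records), flagged)
  mat <- if (length(keep)) {
    do.call(rbind, lapply(records[keep], unclass))
  } else {
    matrix(numeric(0), 0, length(nutrient_slots()),
           dimnames = list(NULL, nutrient_slots()))
  }
  df <- data.frame(participant_id = keep,
                   basis = if (length(records)) bases[keep] else character(0),
                   mat, row.names = NULL, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(exclusions)) {
    utils::write.csv(exclusions, excl_path, row.names = FALSE,
                     fileEncoding = "UTF-8")
  }
  invisible(list(path = path, exclusion_log = if (is.null(exclusions)) NULL else excl_path))
}

#' Read a nutrient table written by [write_nutrients()]
#'
#' @param path CSV path.
#' @return Named list of \code{nutrient_vector}s.
#' @export
read_nutrients <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                        colClasses = c(participant_id = "character"))
  records <- lapply(seq_len(nrow(df)), function(i) {
    nutrient_vector(unlist(df[i, nutrient_slots()]), basis = df$basis[i])
  })
  stats::setNames(records, df$participant_id)
}

#' Nutrient records from a derivation result
#'
#' @param derived A [derive_nutrients()] result.
#' @param basis "weekly" or "daily".
#' @return Named list of \code{nutrient_vector}s for all participants
#'   (exclusion flags travel separately in \code{derived$exclusions}).
#' @export
nutrient_records <- function(derived, basis = c("weekly", "daily")) {
  basis <- match.arg(basis)
  mat <- derived$weekly
  if (basis == "daily") mat <- mat / 7
  stats::setNames(
    lapply(seq_len(nrow(mat)), function(i) nutrient_vector(mat[i, ], basis)),
    rownames(mat))
}
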
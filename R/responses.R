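#' Construct a response set from a data frame
#'
#' The package represents a cohort of questionnaire responses as a data frame
#' with a \code{participant_id} column followed by one character column per
#' answered variable code; missing answers are \code{NA}. Labels are
#' normalised (case, whitespace, dash style) at construction so downstream
#' lookup is exact.
#'
#' @param df Data frame with \code{participant_id} plus variable-code columns.
#' @param schema An [ffq_schema()]; unknown columns are rejected.
#' @param validate_cells When TRUE (default), cells that cannot be parsed for
#'   their item's scale are set missing with a warning naming the column.
#' @return An object of class \code{ffq_responses}.
#' @export
ffq_responses <- function(df, schema = ffq_schema(), validate_cells = TRUE) {
  stopifnot(is.data.frame(df))
  if (!"participant_id" %in% names(df)) {
    stop("responses must have a 'participant_id' column")
  }
  codes <- setdiff(names(df), "participant_id")
  unknown <- setdiff(codes, schema$items$code)
  if (length(unknown)) {
    stop("unknown variable code(s) in responses: ",
         paste(unknown, collapse = ", "))
  }
  ids <- as.character(df$participant_id)
  if (anyDuplicated(ids)) {
    stop("duplicate participant_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  out <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
  for (code in codes) {
    cell <- as.character(df[[code]])
    cell[!is.na(cell) & trimws(cell) == ""] <- NA_character_
    cell <- ifelse(is.na(cell), NA_character_, normalise_label(cell))
    if (validate_cells) {
      cell <- validate_cells_for(code, cell, schema)
    }
    out[[code]] <- cell
  }
  structure(out, class = c("ffq_responses", "data.frame"), schema = schema)
}

validate_cells_for <- function(code, cell, schema) {
  scale <- schema$items$scale[match(code, schema$items$code)]
  ok <- rep(TRUE, length(cell))
  idx <- !is.na(cell)
  if (scale == "weekly5") {
    ok[idx] <- cell[idx] %in% weekly5_labels()
  } else if (scale == "count") {
    ok[idx] <- !is.na(suppressWarnings(as.numeric(cell[idx])))
  } else if (scale == "yesno") {
    ok[idx] <- cell[idx] %in% c("yes", "no")
  }
  if (any(!ok)) {
    warning("column ", code, ": ", sum(!ok),
            " unparseable cell(s) treated as missing", call. = FALSE)
    cell[!ok] <- NA_character_
  }
  cell
}

#' Load questionnaire responses from a delimited-text file
#'
#' Expects a comma-separated UTF-8 file whose header row is
#' \code{participant_id} plus variable codes; empty cells and \code{NA} are
#' missing. Unknown columns are a schema error; duplicate participant ids a
#' load error; unparseable cells become missing with a warning.
#'
#' @param path File path.
#' @inheritParams ffq_responses
#' @return An \code{ffq_responses} object.
#' @export
load_responses <- function(path, schema = ffq_schema()) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        na.strings = c("", "NA"), fileEncoding = "UTF-8")
  ffq_responses(df, schema)
}

#' Write questionnaire responses to a delimited-text file
#'
#' @param responses An \code{ffq_responses} object.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_responses <- function(responses, path) {
  stopifnot(inherits(responses, "ffq_responses"))
  utils::write.csv(as.data.frame(responses), path, row.names = FALSE,
                   na = "", fileEncoding = "UTF-8")
  invisible(path)
}

# One participant's answers as a named list (missing codes absent -> NA on
# lookup via answer_of)
response_row <- function(responses, i) {
  row <- as.list(as.data.frame(responses)[i, , drop = FALSE])
  lapply(row, function(x) if (is.na(x)) NA_character_ else x)
}

answer_of <- function(row, code) {
  v <- row[[code]]
  if (is.null(v)) NA_character_ else v
}
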
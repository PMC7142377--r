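# Strict CSV I/O for the two table schemas.
#
# Long assessment CSV: neonate_id, cohort_id, day_of_life, assessment_index,
# item_id, grade (one row per recorded item grade).  Wide analysis-row CSV:
# neonate_id, cohort_id, treated, analysis_day, original_score,
# simplified_score, one 0/1 column per binary sign.  Parsing is strict:
# typed columns, no silent coercion, errors name the offending lines.

#' Read a long-form assessment CSV
#'
#' @param path CSV path.
#' @param items Item catalogue used for validation.
#' @return Assessment data.frame (see [extract_analysis_rows()]).
#' @export
read_assessments <- function(path, items = fnast_items()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(neonate_id = "character",
                                       cohort_id = "character",
                                       item_id = "character",
                                       grade = "character"))
  req <- c("neonate_id", "cohort_id", "day_of_life", "assessment_index",
           "item_id", "grade")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("day_of_life", "assessment_index")) {
    v <- df[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v != round(v)) || any(v < 1)) {
      bad <- which(is.na(v) | v != round(v) | v < 1)
      stop(path, ": invalid ", col, " at line(s) ",
           paste(utils::head(bad + 1, 5), collapse = ", "), call. = FALSE)
    }
    df[[col]] <- as.integer(v)
  }
  lk <- .item_lookup(items)
  bad_item <- !(df$item_id %in% lk$items)
  if (any(bad_item)) {
    stop(path, ": unknown item_id '", df$item_id[which(bad_item)[1]],
         "' at line ", which(bad_item)[1] + 1, call. = FALSE)
  }
  key <- paste(df$item_id, df$grade, sep = ":")
  bad <- !(key %in% names(lk$weight))
  if (any(bad)) {
    stop(path, ": unknown grade '", df$grade[which(bad)[1]],
         "' for item '", df$item_id[which(bad)[1]], "' at line ",
         which(bad)[1] + 1, call. = FALSE)
  }
  akey <- paste(df$neonate_id, df$day_of_life, df$assessment_index,
                df$item_id)
  if (anyDuplicated(akey)) {
    stop(path, ": duplicated (neonate, day, index, item) at line ",
         which(duplicated(akey))[1] + 1, call. = FALSE)
  }
  df
}

#' Write a long-form assessment CSV
#'
#' @param assessments Assessment data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assessments <- function(assessments, path) {
  utils::write.csv(assessments, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write the wide analysis-row CSV
#'
#' @param path CSV path.
#' @return Analysis-row data.frame.
#' @export
read_analysis_rows <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(neonate_id = "character",
                                       cohort_id = "character"))
  req <- c("neonate_id", "cohort_id", "treated", "analysis_day",
           "original_score", "simplified_score", binary_items())
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$neonate_id)) {
    stop(path, ": duplicated neonate_id at line ",
         which(duplicated(df$neonate_id))[1] + 1, call. = FALSE)
  }
  df$treated <- as.logical(df$treated)
  if (anyNA(df$treated)) stop(path, ": non-boolean treated", call. = FALSE)
  for (id in binary_items()) {
    if (!all(df[[id]] %in% c(0L, 1L))) {
      stop(path, ": column ", id, " must be 0/1", call. = FALSE)
    }
  }
  df
}

#' @rdname read_analysis_rows
#' @param rows Analysis-row data.frame.
#' @export
write_analysis_rows <- function(rows, path) {
  out <- rows
  out$treated <- as.logical(out$treated)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the item catalogue as a versioned JSON resource
#'
#' @param path Output path.
#' @param items Item catalogue.
#' @export
write_item_catalogue <- function(path, items = fnast_items()) {
  jsonlite::write_json(list(version = "1.0", items = items), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
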
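# File round-trips: corpora and annotation streams as JSON Lines (one record
# per line, UTF-8), tables as quoted CSV. Chosen for lossless free text and
# diff-ability.

#' Read and write document corpora as JSON Lines
#'
#' One JSON object per line with fields `doc_id`, `patient_id`, `date`
#' (ISO-8601), `doc_type`, `text`. Free text round-trips losslessly
#' (including newlines, which are JSON-escaped).
#'
#' @param path file path.
#' @param corpus corpus data frame.
#' @return `read_corpus` returns the corpus data frame with `date` as `Date`;
#'   writers return `path` invisibly.
#' @export
read_corpus <- function(path) {
  df <- jsonlite::stream_in(file(path), verbose = FALSE)
  if (nrow(df) == 0L) {
    return(data.frame(doc_id = character(0), patient_id = character(0),
                      date = as.Date(character(0)), doc_type = character(0),
                      text = character(0), stringsAsFactors = FALSE))
  }
  df$date <- as.Date(df$date)
  if (anyDuplicated(df$doc_id)) stop("duplicate doc_id in corpus",
                                     call. = FALSE)
  df
}

#' @rdname read_corpus
#' @export
write_corpus <- function(corpus, path) {
  corpus$date <- as.character(corpus$date)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  jsonlite::stream_out(corpus, con, verbose = FALSE)
  invisible(path)
}

#' Read a corpus from a directory of plain-text files
#'
#' Each `*.txt` file is one document; a sidecar CSV (`metadata`) supplies
#' `doc_id` (the file name without extension), `patient_id`, `date`,
#' `doc_type`.
#'
#' @param dir directory of `.txt` files.
#' @param metadata path to the sidecar metadata CSV.
#' @return a corpus data frame.
#' @export
read_corpus_dir <- function(dir, metadata) {
  meta <- utils::read.csv(metadata, stringsAsFactors = FALSE)
  stopifnot(all(c("doc_id", "patient_id", "date", "doc_type") %in%
                  names(meta)))
  files <- file.path(dir, paste0(meta$doc_id, ".txt"))
  missing <- !file.exists(files)
  if (any(missing)) {
    stop("text file(s) missing for doc_id: ",
         paste(meta$doc_id[missing], collapse = ", "), call. = FALSE)
  }
  meta$text <- vapply(files, function(f) {
    paste(readLines(f, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  }, character(1), USE.NAMES = FALSE)
  meta$date <- as.Date(meta$date)
  meta
}

#' Read and write annotation streams as JSON Lines
#'
#' Fields `doc_id`, `start`, `end` (0-based half-open), `matched_text`,
#' `status`, `rule_id`. Gold-standard files use the same schema (with
#' `rule_id` optional), so engine output can be hand-corrected into gold.
#'
#' @param path file path.
#' @param annotations annotation data frame.
#' @return `read_annotations` returns the data frame; writers return `path`
#'   invisibly.
#' @export
read_annotations <- function(path) {
  df <- jsonlite::stream_in(file(path), verbose = FALSE)
  if (nrow(df) == 0L) return(empty_annotations())
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df
}

#' @rdname read_annotations
#' @export
write_annotations <- function(annotations, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  jsonlite::stream_out(annotations, con, verbose = FALSE)
  invisible(path)
}

#' Attach document dates and patients to annotations
#'
#' Joins annotations to their documents so each text-derived status record
#' carries the `patient_id` and the *document* date (the record date used by
#' the first-record-after-referral rule).
#'
#' @param annotations output of [annotate_corpus()].
#' @param corpus the corpus the annotations came from.
#' @return the annotations with `patient_id` and `date` columns added.
#' @export
annotations_with_dates <- function(annotations, corpus) {
  i <- match(annotations$doc_id, corpus$doc_id)
  if (anyNA(i)) {
    stop("annotations reference doc_ids absent from the corpus",
         call. = FALSE)
  }
  annotations$patient_id <- corpus$patient_id[i]
  annotations$date <- as.Date(corpus$date)[i]
  annotations
}

#' Read and write delimited tables
#'
#' Plain quoted CSV with a header row; dates ISO-8601. Thin wrappers kept for
#' a stable interface.
#'
#' @param path file path.
#' @param table data frame.
#' @return `read_table_csv` returns a data frame; `write_table_csv` returns
#'   `path` invisibly.
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_table_csv
#' @export
write_table_csv <- function(table, path) {
  df <- as.data.frame(table)
  for (col in names(df)) if (inherits(df[[col]], "Date")) {
    df[[col]] <- as.character(df[[col]])
  }
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
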
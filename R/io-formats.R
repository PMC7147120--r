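#' Read a multichannel EEG recording
#'
#' Reads an EEG recording from disk. EDF is the interchange format; a
#' CSV-matrix escape hatch (one row per channel, samples in columns, no
#' header) is provided for small fixtures, with a YAML sidecar
#' `<path>.meta.yaml` supplying `fs`, `channel_labels` and session
#' metadata.
#'
#' @param path path to the file.
#' @param format `"edf"` or `"csv_matrix"`.
#' @return A validated [multichannel_recording()].
#' @export
read_eeg <- function(path, format = c("edf", "csv_matrix")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("format error: file does not exist: ", path)
  rec <- switch(format,
    edf = read_edf(path),
    csv_matrix = read_eeg_csv(path))
  message(sprintf("read_eeg: %d channels x %d samples @ %g Hz from %s",
                  nrow(rec$data), ncol(rec$data), rec$fs, basename(path)))
  rec
}

read_eeg_csv <- function(path) {
  if (file.info(path)$size == 0)
    stop("format error: empty file: ", path)
  mat <- as.matrix(read.csv(path, header = FALSE))
  if (anyNA(mat))
    stop("validation error: ragged or non-numeric CSV matrix ",
         "(channels must share one length): ", path)
  meta_path <- paste0(path, ".meta.yaml")
  if (!file.exists(meta_path))
    stop("format error: sidecar metadata not found: ", meta_path)
  meta <- yaml::read_yaml(meta_path)
  multichannel_recording(
    unname(mat), fs = meta$fs,
    channel_labels = unlist(meta$channel_labels),
    subject_id = meta$subject_id %||% "S00",
    condition = meta$condition %||% "aided",
    presentation_order = meta$presentation_order %||% 1L)
}

#' Write a recording as a CSV matrix with a YAML sidecar
#'
#' Companion writer to `read_eeg(..., format = "csv_matrix")`: one row per
#' channel, no header; metadata goes to `<path>.meta.yaml`.
#'
#' @param rec a [multichannel_recording()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_eeg_csv <- function(rec, path) {
  validate_recording(rec)
  write.table(rec$data, path, sep = ",", row.names = FALSE,
              col.names = FALSE)
  yaml::write_yaml(
    list(fs = rec$fs, channel_labels = rec$channel_labels,
         subject_id = rec$subject_id, condition = rec$condition,
         presentation_order = rec$presentation_order),
    paste0(path, ".meta.yaml"))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a per-subject results table
#'
#' Writes evaluation summaries as RFC-4180 CSV with a header row. All rows
#' must share the schema `subject, band, condition, mean_r, sd_r,
#' lambda_opt, p_vs_null`; an empty input yields a header-only file.
#'
#' @param rows a data.frame (possibly 0-row) with the columns above.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(rows, path) {
  schema <- c("subject", "band", "condition", "mean_r", "sd_r",
              "lambda_opt", "p_vs_null")
  if (is.null(rows) || (is.data.frame(rows) && nrow(rows) == 0L)) {
    rows <- as.data.frame(setNames(rep(list(character(0)), length(schema)),
                                   schema))
  }
  rows <- as.data.frame(rows)
  if (!all(schema %in% names(rows)))
    stop("validation error: rows must carry columns ",
         paste(schema, collapse = ", "))
  ok <- tryCatch({
    write.csv(rows[schema], path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("I/O error: cannot write results table to ", path, ": ",
         conditionMessage(ok))
  invisible(path)
}

#' Read back a results table written by [write_results_table()]
#'
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_results_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
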
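#' Describe the layout of a CSV velocity export
#'
#' Goggle vendors export VVOR recordings with differing column names,
#' delimiters and decimal marks. A dialect object captures one layout; the
#' default matches the generic layout written by [write_fixture_csv()].
#'
#' @param column_time,column_head,column_eye Column name (character) or
#'   1-based index (numeric) of the time stamp, head velocity and eye
#'   velocity columns.
#' @param test_marker Optional column name/index whose runs of equal values
#'   delimit successive test blocks; `NULL` means the whole file is one test.
#' @param delimiter Single field-delimiter character.
#' @param decimal_mark Decimal mark, `"."` or `","` (locale variants).
#' @return An object of class `csv_dialect`.
#' @export
#' @examples
#' csv_dialect()                                   # generic layout
#' csv_dialect(delimiter = ";", decimal_mark = ",") # e.g. central-European locale
csv_dialect <- function(column_time = "Time", column_head = "HeadVelocity",
                        column_eye = "EyeVelocity", test_marker = NULL,
                        delimiter = ",", decimal_mark = ".") {
  cols <- list(column_time, column_head, column_eye)
  ok <- vapply(cols, function(x)
    (is.character(x) || is.numeric(x)) && length(x) == 1L, TRUE)
  if (!all(ok))
    vvor_stop("column references must be single names or indices",
              "vvor_config_error")
  if (anyDuplicated(vapply(cols, as.character, "")))
    vvor_stop("time, head and eye columns must be distinct", "vvor_config_error")
  if (!is.character(delimiter) || nchar(delimiter) != 1L)
    vvor_stop("delimiter must be a single character", "vvor_config_error")
  if (!decimal_mark %in% c(".", ","))
    vvor_stop("decimal_mark must be '.' or ','", "vvor_config_error")
  if (identical(delimiter, decimal_mark))
    vvor_stop("delimiter and decimal_mark must differ", "vvor_config_error")
  structure(list(column_time = column_time, column_head = column_head,
                 column_eye = column_eye, test_marker = test_marker,
                 delimiter = delimiter, decimal_mark = decimal_mark),
            class = "csv_dialect")
}

resolve_column <- function(df, ref, what) {
  if (is.numeric(ref)) {
    if (ref < 1 || ref > ncol(df))
      vvor_stop(sprintf("%s column index %d out of range (%d columns)",
                        what, as.integer(ref), ncol(df)), "vvor_config_error")
    return(as.integer(ref))
  }
  j <- match(ref, names(df))
  if (is.na(j))
    vvor_stop(sprintf("%s column '%s' not found in file", what, ref),
              "vvor_config_error")
  j
}

parse_numeric_column <- function(x, decimal_mark) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  if (decimal_mark != ".") x <- gsub(decimal_mark, ".", x, fixed = TRUE)
  suppressWarnings(as.numeric(x))
}

#' Read a VVOR recording from a CSV export
#'
#' Reads a device CSV export and returns the last recorded test in the file
#' as a [velocity_trace()]. Rows with unparseable numerics in any of the
#' three data columns are dropped (with a message giving the count). When a
#' `test_marker` column is configured, the last maximal run of rows sharing
#' the same marker value is taken as the last test; otherwise the whole file
#' is one test.
#'
#' A gap longer than 5 nominal sample intervals splits the selected block,
#' and only the final near-uniform segment is kept (with a warning):
#' integration and median filtering assume near-uniform sampling.
#'
#' @param path Path to the CSV file.
#' @param dialect A [csv_dialect()] describing the layout.
#' @param sample_rate Nominal sampling rate in Hz; `NULL` infers it from the
#'   median inter-sample interval of the selected block.
#' @return A [velocity_trace()].
#' @export
read_vvor_csv <- function(path, dialect = csv_dialect(), sample_rate = NULL) {
  if (!file.exists(path))
    vvor_stop(sprintf("file not found: %s", path), "vvor_io_error")
  header <- is.character(dialect$column_time) ||
    is.character(dialect$column_head) || is.character(dialect$column_eye)
  df <- utils::read.csv(path, sep = dialect$delimiter,
                        dec = dialect$decimal_mark, header = header,
                        check.names = FALSE, stringsAsFactors = FALSE,
                        blank.lines.skip = TRUE)
  jt <- resolve_column(df, dialect$column_time, "time")
  jh <- resolve_column(df, dialect$column_head, "head velocity")
  je <- resolve_column(df, dialect$column_eye, "eye velocity")

  # select the last test block before numeric cleaning
  if (!is.null(dialect$test_marker)) {
    jm <- resolve_column(df, dialect$test_marker, "test marker")
    runs <- rle(as.character(df[[jm]]))
    last_len <- runs$lengths[length(runs$lengths)]
    df <- df[(nrow(df) - last_len + 1L):nrow(df), , drop = FALSE]
  }
  raw_rows <- nrow(df)

  t <- parse_numeric_column(df[[jt]], dialect$decimal_mark)
  h <- parse_numeric_column(df[[jh]], dialect$decimal_mark)
  e <- parse_numeric_column(df[[je]], dialect$decimal_mark)
  keep <- !(is.na(t) | is.na(h) | is.na(e))
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message(sprintf("read_vvor_csv: dropped %d row(s) with unparseable numerics",
                    n_drop))
  t <- t[keep]; h <- h[keep]; e <- e[keep]
  if (length(t) == 0L)
    vvor_stop("no valid data rows in the selected test block",
              "vvor_empty_error")
  if (any(diff(t) <= 0))
    vvor_stop("time stamps are not strictly increasing after cleaning",
              "vvor_malformed_error")

  # gap policy: keep only the final near-uniform segment
  nominal_dt <- if (is.null(sample_rate)) stats::median(diff(t)) else 1 / sample_rate
  gaps <- which(diff(t) > 5 * nominal_dt)
  if (length(gaps) > 0) {
    start <- gaps[length(gaps)] + 1L
    warning(sprintf(
      "read_vvor_csv: %d sampling gap(s) > 5 nominal intervals; keeping final segment (%d of %d rows)",
      length(gaps), length(t) - start + 1L, length(t)))
    t <- t[start:length(t)]; h <- h[start:length(h)]; e <- e[start:length(e)]
  }
  tr <- velocity_trace(t, h, e, sample_rate = sample_rate,
                       source = sprintf("%s (rows=%d, dropped=%d)",
                                        basename(path), raw_rows, n_drop))
  attr(tr, "rows_read") <- raw_rows
  attr(tr, "rows_dropped") <- n_drop
  tr
}

# Fixed key order used by write_report(); determinism contract.
report_field_order <- c("package", "version", "input", "parameters",
                        "gain_auc", "gain_scp", "spectral", "saccades",
                        "peak_velocities")

# JSON emission with exact float round-trip: doubles are printed with 17
# significant digits (which uniquely determine the binary value) and always
# carry a decimal point or exponent so they re-parse as doubles, never as
# integers. jsonlite prints one ulp off at full precision, so the report
# writer emits its (flat, two-level) structure itself.
json_scalar <- function(x) {
  if (is.character(x)) {
    x <- gsub("\\", "\\\\", x, fixed = TRUE)
    x <- gsub("\"", "\\\"", x, fixed = TRUE)
    return(sprintf("\"%s\"", x))
  }
  if (is.logical(x)) return(if (x) "true" else "false")
  if (is.integer(x)) return(sprintf("%d", x))
  if (!is.finite(x)) return("null")
  s <- sprintf("%.17g", x)
  if (!grepl("[.eE]", s)) s <- paste0(s, ".0")
  s
}

json_emit <- function(x, indent = "") {
  if (is.null(x)) return("null")
  if (is.list(x)) {
    inner <- paste0(indent, "  ")
    items <- vapply(names(x), function(nm)
      sprintf("%s\"%s\": %s", inner, nm, json_emit(x[[nm]], inner)), "")
    return(sprintf("{\n%s\n%s}", paste(items, collapse = ",\n"), indent))
  }
  if (length(x) != 1L)
    return(sprintf("[%s]", paste(vapply(x, json_scalar, ""), collapse = ", ")))
  json_scalar(x)
}

#' Write a machine-readable analysis report
#'
#' Emits the assembled results of a full analysis ([run_analyze()] or
#' [analyze_trace()]) as structured JSON-compatible text with a fixed key
#' order and full float precision, so that identical analyses produce
#' byte-identical reports and reports re-parse ([read_report()]) to the same
#' values.
#'
#' @param results A `vvor_analysis` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  if (!inherits(results, "vvor_analysis"))
    vvor_stop("results must be a vvor_analysis object", "vvor_report_error")
  required <- c("gain_auc", "gain_scp", "spectral", "saccades")
  missing <- required[vapply(results[required], is.null, TRUE)]
  if (length(missing) > 0)
    vvor_stop(sprintf("incomplete results: missing %s",
                      paste(missing, collapse = ", ")),
              "vvor_report_error")
  rep <- list(
    package = "vvorkit",
    version = as.character(utils::packageVersion("vvorkit")),
    input = results$input,
    parameters = results$parameters,
    gain_auc = list(
      G_AUCp = results$gain_auc$g_pos, G_AUCn = results$gain_auc$g_neg,
      n_runs_pos = results$gain_auc$n_runs_pos,
      n_runs_neg = results$gain_auc$n_runs_neg),
    gain_scp = list(
      G_SPp = results$gain_scp$g_pos, G_SPn = results$gain_scp$g_neg,
      n_runs_pos = results$gain_scp$n_runs_pos,
      n_runs_neg = results$gain_scp$n_runs_neg),
    spectral = list(
      dominant_freq_hz = results$spectral$dominant_freq,
      bin_width_hz = results$spectral$bin_width),
    saccades = list(
      total_count = results$saccades$total_count,
      per_second = results$saccades$per_second,
      per_cycle = results$saccades$per_cycle),
    peak_velocities = list(
      head = results$peak_velocities$head,
      eye = results$peak_velocities$eye)
  )
  rep <- rep[report_field_order]
  con <- tryCatch(file(path, open = "wb"), error = function(e)
    vvor_stop(sprintf("cannot open report path for writing: %s", path),
              "vvor_io_error"))
  on.exit(close(con))
  writeLines(json_emit(rep), con, useBytes = TRUE)
  invisible(path)
}

#' Read back an analysis report written by [write_report()]
#'
#' @param path Path to a report file.
#' @return The parsed report as a named list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
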
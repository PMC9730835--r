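# Tabular IO. CSV, UTF-8, comma-delimited, '.' decimal regardless of
# locale; score/diagnostic outputs rounded to 6 significant digits with a
# fixed column order so identical runs produce byte-identical files.

#' Read a field table from CSV
#'
#' Parses the flat one-row-per-field-year CSV (see [soil_properties()]
#' and [validate_field_table()] for the schema) with locale-independent
#' numeric parsing, then validates. Invalid rows either abort with
#' row-level messages (`on_invalid = "fail"`) or are dropped and
#' reported (`"skip"`).
#'
#' @param path CSV file.
#' @param on_invalid `"fail"` or `"skip"`.
#' @return validated field table tibble; the issue report is attached as
#'   attribute `"issues"`.
#' @export
read_field_table <- function(path, on_invalid = c("fail", "skip")) {
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path)) {
    stop(input_error(sprintf("field table not found: %s", path)))
  }
  header <- strsplit(readLines(path, n = 1), ",", fixed = TRUE)[[1]]
  char_cols <- intersect(
    c(context_columns()[context_columns() != "year_age"], vsa_columns()),
    header
  )
  df <- readr::read_csv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = do.call(
      readr::cols,
      c(stats::setNames(
        rep(list(readr::col_character()), length(char_cols)), char_cols
      ), list(.default = readr::col_guess()))
    ),
    locale = readr::locale(decimal_mark = ".", grouping_mark = ",")
  )
  res <- validate_field_table(df, on_invalid = on_invalid)
  structure(res$records, issues = res$issues)
}

#' Write a field table to CSV
#'
#' Columns are emitted in the fixed schema order (context, properties,
#' VSA items); numeric values keep full precision so a write -> read
#' round trip preserves the records exactly.
#'
#' @param records field table tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_field_table <- function(records, path) {
  cols <- intersect(field_table_columns(), names(records))
  extra <- setdiff(names(records), cols)
  readr::write_csv(records[, c(cols, extra)], path, progress = FALSE)
  invisible(path)
}

round_numeric <- function(df, digits = 6) {
  for (col in names(df)) {
    if (is.numeric(df[[col]])) df[[col]] <- signif(df[[col]], digits)
  }
  df
}

#' Write a score (or any result) table to CSV
#'
#' Numeric columns are rounded to 6 significant digits for reproducible
#' diffs.
#'
#' @param scores tibble, e.g. from [score_fields()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path) {
  readr::write_csv(round_numeric(scores), path, progress = FALSE, na = "")
  invisible(path)
}
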
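# Field-table schema: one row per field-year, flat CSV-friendly columns.

#' Enumerations used by the field-table schema
#'
#' `soil_types()`, `land_uses()`, `groundwater_classes()` and `vsa_items()`
#' return the controlled vocabularies of the framework. Groundwater classes
#' are ordinal, listed from shallow (I) to deep (VIII), mirroring the Dutch
#' Gt classification.
#'
#' @return character vector of allowed values.
#' @export
soil_types <- function() c("sand", "clay", "loess", "peat")

#' @rdname soil_types
#' @export
land_uses <- function() c("grassland", "maize", "arable")

#' @rdname soil_types
#' @export
groundwater_classes <- function() {
  c("I", "II", "III", "IV", "V", "VI", "VII", "VIII")
}

#' @rdname soil_types
#' @export
vsa_items <- function() {
  c("earthworms", "compaction", "gray_spots", "ponding", "cracks",
    "bio_pores", "rooting_depth", "structure", "crop_cover")
}

vsa_columns <- function() paste0("vsa_", vsa_items())

vsa_ratings <- function() c("poor", "moderate", "good")

#' Measured soil properties understood by the framework
#'
#' Returns the property schema: column name, unit and the plausibility
#' range enforced by [validate_field_table()]. Concentrations are per kg
#' dry soil; CEC occupancies are percentages of CEC; `management_score`
#' is a config-supplied 0--1 sub-score from an external management
#' evaluation scheme.
#'
#' @return tibble with columns `property`, `unit`, `lower`, `upper`.
#' @export
soil_properties <- function() {
  tibble::tribble(
    ~property,          ~unit,        ~lower, ~upper,
    "organic_matter",   "% dry soil", 0,      100,
    "ph",               "-",          2,      11,
    "clay",             "%",          0,      100,
    "silt",             "%",          0,      100,
    "sand",             "%",          0,      100,
    "n_total",          "mg N/kg",    0,      Inf,
    "p_avail",          "mg P/kg",    0,      Inf,
    "k_avail",          "mg K/kg",    0,      Inf,
    "mg_avail",         "mg Mg/kg",   0,      Inf,
    "cu_avail",         "mg Cu/kg",   0,      Inf,
    "s_avail",          "mg S/kg",    0,      Inf,
    "zn_avail",         "mg Zn/kg",   0,      Inf,
    "cec",              "mmol+/kg",   0,      Inf,
    "cec_occ_ca",       "% of CEC",   0,      100,
    "cec_occ_mg",       "% of CEC",   0,      100,
    "cec_occ_k",        "% of CEC",   0,      100,
    "pmn",              "mg N/kg",    0,      Inf,
    "bulk_density",     "g/cm3",      0.1,    2.2,
    "management_score", "0-1",        0,      1
  )
}

context_columns <- function() {
  c("field_id", "year_age", "soil_type", "land_use", "groundwater_class",
    "crop_code")
}

mandatory_columns <- function() {
  c("field_id", "year_age", "soil_type", "land_use")
}

field_table_columns <- function() {
  c(context_columns(), soil_properties()$property, vsa_columns())
}

#' Validate a field table
#'
#' Checks a flat field-year table (one row per field per year) against the
#' schema: mandatory context columns, controlled vocabularies, property
#' plausibility ranges, texture closure (clay + silt + sand within
#' \[99, 101\] when all three are present), year ages in 0--9 and unique
#' per field, and all-or-none completeness of the nine VSA items. Unknown
#' columns trigger a warning but are kept.
#'
#' @param df data frame of field-year rows.
#' @param on_invalid `"fail"` to stop on the first report of invalid rows,
#'   `"skip"` to drop invalid rows and return them in the issue report.
#' @return list with `records` (validated tibble) and `issues` (tibble of
#'   `row`, `column`, `message` for every violation found).
#' @export
validate_field_table <- function(df, on_invalid = c("fail", "skip")) {
  on_invalid <- match.arg(on_invalid)
  df <- tibble::as_tibble(df)

  missing_cols <- setdiff(mandatory_columns(), names(df))
  if (length(missing_cols) > 0) {
    stop(input_error(sprintf(
      "field table is missing mandatory column(s): %s",
      paste(missing_cols, collapse = ", ")
    )))
  }
  unknown <- setdiff(names(df), field_table_columns())
  if (length(unknown) > 0) {
    warning(sprintf(
      "ignoring unknown field-table column(s): %s",
      paste(unknown, collapse = ", ")
    ), call. = FALSE)
  }

  issues <- list()
  flag <- function(rows, column, message) {
    rows <- which(rows)
    if (length(rows) > 0) {
      issues[[length(issues) + 1]] <<-
        tibble::tibble(row = rows, column = column, message = message)
    }
  }

  n <- nrow(df)
  flag(is.na(df$field_id) | !nzchar(as.character(df$field_id)),
       "field_id", "field_id must be non-empty")
  ya <- suppressWarnings(as.numeric(df$year_age))
  flag(is.na(ya) | ya != round(ya) | ya < 0 | ya > 9,
       "year_age", "year_age must be an integer in [0, 9]")
  dup <- duplicated(df[, c("field_id", "year_age")])
  flag(dup, "year_age", "duplicate field_id x year_age")
  flag(!is.na(df$soil_type) & !(df$soil_type %in% soil_types()),
       "soil_type", sprintf("soil_type must be one of %s",
                            paste(soil_types(), collapse = "/")))
  flag(is.na(df$soil_type), "soil_type", "soil_type is required")
  flag(!is.na(df$land_use) & !(df$land_use %in% land_uses()),
       "land_use", sprintf("land_use must be one of %s",
                           paste(land_uses(), collapse = "/")))
  flag(is.na(df$land_use), "land_use", "land_use is required")
  if ("groundwater_class" %in% names(df)) {
    flag(!is.na(df$groundwater_class) &
           !(df$groundwater_class %in% groundwater_classes()),
         "groundwater_class", "unknown groundwater class")
  }

  props <- soil_properties()
  for (i in seq_len(nrow(props))) {
    p <- props$property[i]
    if (!p %in% names(df)) next
    x <- df[[p]]
    if (!is.numeric(x)) {
      flag(rep(TRUE, n), p, sprintf("%s must be numeric", p))
      next
    }
    flag(!is.na(x) & (x < props$lower[i] | x > props$upper[i]), p,
         sprintf("%s outside [%g, %g] %s", p, props$lower[i],
                 props$upper[i], props$unit[i]))
  }
  if (all(c("clay", "silt", "sand") %in% names(df))) {
    tex <- df$clay + df$silt + df$sand
    flag(!is.na(tex) & (tex < 99 | tex > 101), "clay",
         "texture fractions must sum to 100 (+/- 1)")
  }

  present_vsa <- intersect(vsa_columns(), names(df))
  if (length(present_vsa) > 0) {
    vsa_mat <- as.matrix(df[, present_vsa, drop = FALSE])
    bad_rating <- !is.na(vsa_mat) & !(vsa_mat %in% vsa_ratings())
    flag(rowSums(bad_rating) > 0, "vsa",
         "VSA ratings must be poor/moderate/good")
    n_given <- rowSums(!is.na(vsa_mat))
    full <- length(vsa_columns())
    flag(n_given > 0 & (n_given < full | length(present_vsa) < full), "vsa",
         "a VSA record must supply all nine items")
  }

  issues <- if (length(issues) > 0) {
    dplyr::distinct(dplyr::bind_rows(issues))
  } else {
    tibble::tibble(row = integer(), column = character(),
                   message = character())
  }

  if (nrow(issues) > 0) {
    msgs <- sprintf("row %d [%s]: %s", issues$row, issues$column,
                    issues$message)
    if (on_invalid == "fail") {
      stop(input_error(paste(
        c(sprintf("%d invalid field-table row report(s):", nrow(issues)),
          utils::head(msgs, 10),
          if (length(msgs) > 10) sprintf("... and %d more", length(msgs) - 10)),
        collapse = "\n"
      )))
    }
    df <- df[-unique(issues$row), , drop = FALSE]
  }
  df$year_age <- as.integer(df$year_age)
  ordered_cols <- c(intersect(field_table_columns(), names(df)),
                    setdiff(names(df), field_table_columns()))
  list(records = df[, ordered_cols], issues = issues)
}
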
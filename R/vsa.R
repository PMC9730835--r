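# Visual soil assessment (VSA): nine in-field items rated
# poor/moderate/good. Ratings for soil structure and compaction replace
# the model-derived aggregate-stability and compaction indicators.

#' Score one VSA rating on the indicator scale
#'
#' Maps the three-level field rating onto the 0--1 indicator scale:
#' poor = 0, moderate = 0.5, good = 1 (midpoint convention, aligning the
#' qualitative scale with the "fertilization recommended" anchor).
#'
#' @param rating character vector of ratings.
#' @return numeric vector in \{0, 0.5, 1\}; `NA` propagates.
#' @export
vsa_item_score <- function(rating) {
  map <- c(poor = 0, moderate = 0.5, good = 1)
  rating <- as.character(rating)
  bad <- !is.na(rating) & !(rating %in% names(map))
  if (any(bad)) {
    stop(input_error(sprintf(
      "unknown VSA rating(s): %s (expected poor/moderate/good)",
      paste(sQuote(unique(rating[bad])), collapse = ", ")
    )))
  }
  unname(map[rating])
}

#' Overall VSA score of a field visit
#'
#' Arithmetic mean of the nine item scores. The record must be complete:
#' a partial visual assessment is rejected.
#'
#' @param vsa either a named character vector/list with all nine items
#'   (names as in [vsa_items()]) or a one-row data frame with `vsa_*`
#'   columns.
#' @return mean score in \[0, 1\].
#' @examples
#' vsa_overall(setNames(rep("moderate", 9), vsa_items()))  # 0.5
#' @export
vsa_overall <- function(vsa) {
  if (is.data.frame(vsa)) {
    if (nrow(vsa) != 1) stop(input_error("vsa_overall expects one record"))
    cols <- vsa_columns()
    if (!all(cols %in% names(vsa))) {
      stop(input_error("VSA record must supply all nine vsa_* columns"))
    }
    ratings <- as.character(unlist(vsa[, cols]))
    names(ratings) <- vsa_items()
  } else {
    ratings <- unlist(vsa)
    if (!all(vsa_items() %in% names(ratings))) {
      stop(input_error(sprintf(
        "VSA record must rate all nine items (%s)",
        paste(vsa_items(), collapse = ", ")
      )))
    }
    ratings <- ratings[vsa_items()]
  }
  if (anyNA(ratings)) {
    stop(input_error("VSA record is incomplete (NA ratings)"))
  }
  mean(vsa_item_score(ratings))
}

#' Substitute VSA ratings into an evaluated indicator table
#'
#' For every battery entry declaring a `vsa_item` (by default the
#' compaction and aggregate-stability functions), field-years whose
#' record carries a complete VSA get that item's rating score in place of
#' the model-derived indicator value, with `source` set to `"vsa"`. All
#' other indicators, and records without VSA, are untouched; the
#' operation is idempotent.
#'
#' @param indicators long indicator table from [evaluate_battery()].
#' @param records the field table the indicators were evaluated from.
#' @param battery the `indicator_battery` used.
#' @return the indicator table with substitutions applied.
#' @export
apply_vsa <- function(indicators, records, battery = default_battery()) {
  battery <- validate_battery(battery)
  subs <- purrr::keep(battery$functions, function(d) !is.null(d$vsa_item))
  if (length(subs) == 0) return(indicators)
  for (d in subs) {
    col <- paste0("vsa_", d$vsa_item)
    if (!col %in% names(records)) next
    ratings <- tibble::tibble(
      field_id = records$field_id,
      year_age = records$year_age,
      .rating = records[[col]]
    )
    idx <- indicators$function_id == d$id
    sub <- dplyr::left_join(indicators[idx, c("field_id", "year_age")],
                            ratings, by = c("field_id", "year_age"))
    has <- !is.na(sub$.rating)
    if (!any(has)) next
    which_idx <- which(idx)[has]
    indicators$value[which_idx] <- vsa_item_score(sub$.rating[has])
    indicators$source[which_idx] <- "vsa"
  }
  indicators
}
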
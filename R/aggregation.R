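# Three-step weighted aggregation: indicators -> category-year scores ->
# category sub-scores -> final score. Each step applies a correction
# factor: distance-to-target weighting (step 1), crop recency (step 2),
# indicator count per category (step 3).

#' Aggregation configuration
#'
#' Bundles the correction-factor parameters of the three aggregation
#' steps. Defaults: distance-to-target offset `c = 0.2`
#' (step-1 weight `1/(I + c)`), year weights 1.0 for crops younger than
#' `recent_horizon = 5` years and 0.5 otherwise (step 2), and
#' `log2(n + 1)` category weights so categories backed by more measured
#' indicators count more, with diminishing returns (step 3).
#'
#' @param c distance-to-target offset, must be > 0; smaller values put
#'   more weight on the most limiting (lowest) indicator.
#' @param recent_weight,old_weight year weights for recent / older crops.
#' @param recent_horizon year-age threshold separating recent from old.
#' @param category_weight function of the indicator count `n` returning
#'   the step-3 weight; must return 0 only for `n = 0`.
#' @param include_management if `FALSE` the management category is
#'   excluded from the final score (useful when management properties are
#'   regional defaults rather than field observations).
#' @return an `aggregation_config` list.
#' @export
aggregation_config <- function(c = 0.2, recent_weight = 1.0,
                               old_weight = 0.5, recent_horizon = 5,
                               category_weight = function(n) log2(n + 1),
                               include_management = TRUE) {
  if (!is.numeric(c) || length(c) != 1 || is.na(c) || c <= 0) {
    stop(config_error("distance-to-target offset c must be > 0"))
  }
  if (recent_weight <= 0 || old_weight <= 0) {
    stop(config_error("year weights must be > 0"))
  }
  if (!is.function(category_weight) || category_weight(0) != 0) {
    stop(config_error("category_weight must be a function with f(0) = 0"))
  }
  structure(
    list(c = c, recent_weight = recent_weight, old_weight = old_weight,
         recent_horizon = recent_horizon, category_weight = category_weight,
         include_management = include_management),
    class = "aggregation_config"
  )
}

#' Distance-to-target weight (step-1 correction factor)
#'
#' `w = 1 / (I + c)`: following the law of the minimum, the lowest
#' indicator -- presumed the most limiting factor for crop production --
#' receives the largest weight. Strictly decreasing in `I`, finite and
#' positive for all `I` in \[0, 1\] when `c > 0`.
#'
#' @param i indicator value(s) in \[0, 1\].
#' @param c offset > 0.
#' @return numeric weight(s).
#' @examples
#' weight_distance_to_target(c(0.2, 1.0), c = 0.2)  # 2.5, 0.833
#' @export
weight_distance_to_target <- function(i, c = 0.2) {
  if (!is.numeric(c) || length(c) != 1 || is.na(c) || c <= 0) {
    stop(config_error("distance-to-target offset c must be > 0"))
  }
  1 / (i + c)
}

#' Step 1: aggregate indicators within one category-year
#'
#' Weighted mean of the non-missing indicator values with
#' distance-to-target weights; missing indicators are excluded (weights
#' renormalize automatically). Always lies between the minimum and the
#' unweighted mean of its inputs.
#'
#' @param values indicator values in \[0, 1\], `NA` allowed.
#' @param c distance-to-target offset.
#' @return the category-year score, or `NA` when all inputs are missing.
#' @examples
#' aggregate_within_category(c(0.2, 1.0), c = 0.2)  # 0.4
#' @export
aggregate_within_category <- function(values, c = 0.2) {
  v <- values[!is.na(values)]
  if (length(v) == 0) return(NA_real_)
  w <- weight_distance_to_target(v, c)
  sum(w * v) / sum(w)
}

year_weight <- function(year_age, cfg) {
  ifelse(year_age < cfg$recent_horizon, cfg$recent_weight, cfg$old_weight)
}

#' Step 2: aggregate one category's yearly scores across the record
#'
#' Weighted mean over years with recency weights (more weight on recent
#' crops); years with a missing category score are excluded and the
#' weights renormalize.
#'
#' @param scores per-year category scores, `NA` allowed.
#' @param ages matching year ages (0 = most recent).
#' @param cfg [aggregation_config()].
#' @return the multi-year category sub-score, `NA` if no year has a score.
#' @examples
#' aggregate_years(c(rep(1, 5), rep(0, 5)), 0:9)  # 0.6667
#' @export
aggregate_years <- function(scores, ages, cfg = aggregation_config()) {
  stopifnot(length(scores) == length(ages))
  keep <- !is.na(scores)
  if (!any(keep)) return(NA_real_)
  w <- year_weight(ages[keep], cfg)
  sum(w * scores[keep]) / sum(w)
}

#' Step-3 correction factor: category weight from indicator count
#'
#' Default `log2(n + 1)`: a category underpinned by more measured soil
#' functions is better supported and weighs more, with diminishing
#' returns. Zero exactly when the category contributed no indicators.
#'
#' @param n_k non-negative integer count(s) of contributing indicators.
#' @param cfg [aggregation_config()].
#' @return numeric weight(s).
#' @export
weight_category <- function(n_k, cfg = aggregation_config()) {
  if (any(is.na(n_k)) || any(n_k < 0)) {
    stop(input_error("indicator counts must be non-negative"))
  }
  cfg$category_weight(n_k)
}

#' Step 3: aggregate category sub-scores into the final score
#'
#' Weighted mean of the category sub-scores with indicator-count weights.
#' Categories with no contributing indicators (or a missing sub-score)
#' are excluded; the management category is excluded when the
#' configuration says so.
#'
#' @param scores named numeric vector of category sub-scores (names are
#'   categories).
#' @param n_k matching counts of contributing indicators.
#' @param cfg [aggregation_config()].
#' @return final score in \[0, 1\].
#' @examples
#' aggregate_categories(
#'   c(chemical = 0.8, physical = 0.6, biological = 0.9, environmental = 0.7),
#'   n_k = c(9, 8, 2, 2)
#' )  # 0.7344
#' @export
aggregate_categories <- function(scores, n_k, cfg = aggregation_config()) {
  stopifnot(length(scores) == length(n_k))
  keep <- !is.na(scores) & n_k >= 1
  if (!is.null(names(scores)) && !cfg$include_management) {
    keep <- keep & names(scores) != "management"
  }
  if (!any(keep)) {
    stop(input_error("no category with at least one indicator to aggregate"))
  }
  w <- weight_category(n_k[keep], cfg)
  sum(w * scores[keep]) / sum(w)
}

#' Aggregate a single indicator vector to category and final scores
#'
#' Convenience fast path for one field-year: runs step 1 per category and
#' step 3 across categories (step 2 is the identity for a single year).
#' Used by the aggregation-method diagnostics and property checks.
#'
#' @param values indicator values, `NA` allowed.
#' @param categories matching category labels.
#' @param cfg [aggregation_config()].
#' @param weighting `"nonlinear"` for distance-to-target step-1 weights,
#'   `"equal"` for plain within-category means (the step-3 count weights
#'   are kept in both cases so the methods stay comparable).
#' @return list with `category_scores` (named), `n_k` (named) and `final`.
#' @export
aggregate_vector <- function(values, categories, cfg = aggregation_config(),
                             weighting = c("nonlinear", "equal")) {
  weighting <- match.arg(weighting)
  stopifnot(length(values) == length(categories))
  keep <- !is.na(values)
  groups <- split(values[keep], as.character(categories[keep]))
  s_k <- vapply(groups, function(v) {
    if (weighting == "nonlinear") {
      aggregate_within_category(v, cfg$c)
    } else {
      mean(v)
    }
  }, numeric(1))
  n_k <- lengths(groups)
  list(category_scores = s_k, n_k = n_k,
       final = aggregate_categories(s_k, n_k, cfg))
}

# Shared scoring pipeline over a (possibly multi-field) long indicator
# table. Returns the per-year, per-category and final pieces.
score_indicator_table <- function(indicators, cfg) {
  step1 <- indicators |>
    dplyr::mutate(.w = 1 / (.data$value + cfg$c)) |>
    dplyr::group_by(.data$field_id, .data$year_age, .data$category) |>
    dplyr::summarise(
      n = sum(!is.na(.data$value)),
      score = sum(.data$.w * .data$value, na.rm = TRUE) /
        sum(.data$.w, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(score = ifelse(.data$n == 0, NA_real_, .data$score))

  step2 <- step1 |>
    dplyr::mutate(.yw = year_weight(.data$year_age, cfg)) |>
    dplyr::group_by(.data$field_id, .data$category) |>
    dplyr::summarise(
      score = {
        ok <- !is.na(.data$score)
        if (any(ok)) {
          sum(.data$.yw[ok] * .data$score[ok]) / sum(.data$.yw[ok])
        } else {
          NA_real_
        }
      },
      .groups = "drop"
    )

  # n_k = number of distinct soil functions contributing to the category
  # in at least one year of the record
  n_k <- indicators |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::distinct(.data$field_id, .data$category, .data$function_id) |>
    dplyr::count(.data$field_id, .data$category, name = "n_k")

  step2 <- step2 |>
    dplyr::left_join(n_k, by = c("field_id", "category")) |>
    dplyr::mutate(
      n_k = dplyr::coalesce(.data$n_k, 0L),
      weight = ifelse(
        !cfg$include_management & .data$category == "management",
        0, weight_category(.data$n_k, cfg)
      )
    )

  final <- step2 |>
    dplyr::filter(.data$weight > 0, !is.na(.data$score)) |>
    dplyr::group_by(.data$field_id) |>
    dplyr::summarise(
      final_score = sum(.data$weight * .data$score) / sum(.data$weight),
      .groups = "drop"
    ) |>
    dplyr::mutate(class = classify_score(.data$final_score))

  list(per_year = step1, per_category = step2, final = final)
}

#' Score many fields at once
#'
#' Evaluates the battery on every field-year record, optionally
#' substitutes VSA ratings, and runs the three aggregation steps per
#' field. This is the bulk entry point used for survey-scale runs.
#'
#' @param records validated field table (any number of fields).
#' @param battery `indicator_battery`; defaults to [default_battery()].
#' @param cfg [aggregation_config()].
#' @param use_vsa replace model-derived compaction / aggregate-stability
#'   indicators with VSA ratings where present.
#' @return tibble with one row per field: category sub-score columns,
#'   `final_score` and interpretation `class`.
#' @export
score_fields <- function(records, battery = default_battery(),
                         cfg = aggregation_config(), use_vsa = TRUE) {
  battery <- validate_battery(battery)
  indicators <- evaluate_battery(battery, records)
  if (use_vsa) indicators <- apply_vsa(indicators, records, battery)
  parts <- score_indicator_table(indicators, cfg)
  wide <- parts$per_category |>
    dplyr::select("field_id", "category", "score") |>
    tidyr::pivot_wider(names_from = "category", values_from = "score")
  dplyr::left_join(wide, parts$final, by = "field_id")
}

#' Score one field and keep full provenance
#'
#' Runs the same pipeline as [score_fields()] for a single field but
#' returns a `score_report` retaining every intermediate: per-year
#' category scores, multi-year category sub-scores with their counts and
#' weights, the evaluated indicators, and the weights actually used.
#'
#' @param records validated field table rows of one field.
#' @param battery `indicator_battery`.
#' @param cfg [aggregation_config()].
#' @param use_vsa replace VSA-substitutable indicators where ratings exist.
#' @return a `score_report` object; see [as_json.score_report()].
#' @export
score_field <- function(records, battery = default_battery(),
                        cfg = aggregation_config(), use_vsa = TRUE) {
  ids <- unique(records$field_id)
  if (length(ids) != 1) {
    stop(input_error(sprintf(
      "score_field expects one field, got %d ids (%s)",
      length(ids), paste(utils::head(ids, 5), collapse = ", ")
    )))
  }
  battery <- validate_battery(battery)
  indicators <- evaluate_battery(battery, records)
  if (use_vsa) indicators <- apply_vsa(indicators, records, battery)
  parts <- score_indicator_table(indicators, cfg)
  structure(
    list(
      field_id = ids,
      indicators = indicators,
      per_year = parts$per_year,
      category_scores = parts$per_category,
      final_score = parts$final$final_score,
      class = parts$final$class,
      weights = list(
        distance_to_target_offset = cfg$c,
        year = tibble::tibble(
          year_age = sort(unique(records$year_age)),
          weight = year_weight(sort(unique(records$year_age)), cfg)
        ),
        category = parts$per_category[, c("category", "n_k", "weight")]
      )
    ),
    class = "score_report"
  )
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("<score_report> field %s\n", x$field_id))
  cs <- x$category_scores
  for (i in seq_len(nrow(cs))) {
    cat(sprintf("  %-13s %s  (n = %d, weight = %.3f)\n", cs$category[i],
                formatC(cs$score[i], digits = 3, format = "f"),
                cs$n_k[i], cs$weight[i]))
  }
  cat(sprintf("  final score   %.3f  [%s]\n", x$final_score, x$class))
  invisible(x)
}

#' Serialize a score report to JSON
#'
#' Nested JSON mirroring the aggregation hierarchy: per-year category
#' scores, category sub-scores with counts and weights, final score,
#' class, and the weights used.
#'
#' @param x a `score_report`.
#' @param ... unused.
#' @return JSON string (class `json`).
#' @export
as_json <- function(x, ...) UseMethod("as_json")

#' @rdname as_json
#' @export
as_json.score_report <- function(x, ...) {
  jsonlite::toJSON(
    list(
      field_id = x$field_id,
      final_score = x$final_score,
      class = x$class,
      category_scores = x$category_scores,
      per_year = x$per_year,
      weights = list(
        distance_to_target_offset = x$weights$distance_to_target_offset,
        year = x$weights$year,
        category = x$weights$category
      )
    ),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )
}
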
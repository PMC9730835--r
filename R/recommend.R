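# Recommendation engine: rank farming practices by how effectively they
# improve the poorly scored soil functions of each category.

#' Read a practice catalogue and effectiveness matrix
#'
#' The config lists the available farming practices (with land-use and
#' soil-type applicability filters, `"*"` = any) and a sparse
#' practice x soil-function effectiveness matrix with entries in
#' \[0, 1\]; pairs not listed have effectiveness 0.
#'
#' @param path YAML or JSON file; see
#'   `inst/extdata/practices-default.yaml` for the schema.
#' @return list with tibbles `practices` (`practice_id`, `label`,
#'   `land_uses`, `soil_types` list-columns) and `effectiveness`
#'   (`practice_id`, `function_id`, `e`).
#' @export
read_practices <- function(path) {
  if (!file.exists(path)) {
    stop(config_error(sprintf("practice config not found: %s", path)))
  }
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$practices) || is.null(cfg$effectiveness)) {
    stop(config_error(
      "practice config needs 'practices' and 'effectiveness' sections"
    ))
  }
  practices <- tibble::tibble(
    practice_id = vapply(cfg$practices, `[[`, character(1), "id"),
    label = vapply(cfg$practices, `[[`, character(1), "label"),
    land_uses = lapply(cfg$practices, function(p) unlist(p$land_uses)),
    soil_types = lapply(cfg$practices, function(p) unlist(p$soil_types))
  )
  if (anyDuplicated(practices$practice_id)) {
    stop(config_error("duplicate practice ids"))
  }
  empty <- lengths(practices$land_uses) == 0 | lengths(practices$soil_types) == 0
  if (any(empty)) {
    stop(config_error(sprintf(
      "practice(s) with empty applicability: %s",
      paste(practices$practice_id[empty], collapse = ", ")
    )))
  }
  eff <- tibble::tibble(
    practice_id = vapply(cfg$effectiveness, `[[`, character(1), "practice"),
    function_id = vapply(cfg$effectiveness, `[[`, character(1), "function"),
    e = vapply(cfg$effectiveness, function(x) as.numeric(x$e), numeric(1))
  )
  if (any(is.na(eff$e) | eff$e < 0 | eff$e > 1)) {
    stop(config_error("effectiveness values must lie in [0, 1]"))
  }
  if (!all(eff$practice_id %in% practices$practice_id)) {
    stop(config_error("effectiveness entry references unknown practice"))
  }
  list(practices = practices, effectiveness = eff)
}

#' @rdname read_practices
#' @export
default_practices <- function() {
  read_practices(system.file("extdata", "practices-default.yaml",
                             package = "soilscore", mustWork = TRUE))
}

applicable_practices <- function(practices, land_use, soil_type) {
  ok <- vapply(seq_len(nrow(practices)), function(i) {
    lu <- practices$land_uses[[i]]
    st <- practices$soil_types[[i]]
    ("*" %in% lu || land_use %in% lu) && ("*" %in% st || soil_type %in% st)
  }, logical(1))
  practices[ok, , drop = FALSE]
}

#' Recommend the best practice for one category
#'
#' Scores every applicable practice by its expected benefit
#' `sum over functions f in the category of e(p, f) * (1 - I_f)`:
#' effectiveness times the distance to target, so practices that act on
#' the most deficient functions rank highest. Missing indicators are
#' skipped (their deficiency is unknown). Ties break lexicographically by
#' practice id, making the ranking deterministic.
#'
#' @param indicators indicator table of one field-year (columns
#'   `function_id`, `category`, `value`), typically after [apply_vsa()].
#' @param category category to advise on.
#' @param practices practice catalogue from [read_practices()].
#' @param land_use,soil_type applicability context of the field.
#' @return tibble ranked by descending benefit with columns `category`,
#'   `practice_id`, `label`, `benefit`, `rank`, `best`, `no_deficiency`.
#'   Zero rows (with a warning) when no practice is applicable.
#' @export
recommend_category <- function(indicators, category,
                               practices = default_practices(),
                               land_use, soil_type) {
  cand <- applicable_practices(practices$practices, land_use, soil_type)
  if (nrow(cand) == 0) {
    warning(sprintf("no applicable practice for %s/%s", land_use, soil_type),
            call. = FALSE)
    return(tibble::tibble(
      category = character(), practice_id = character(), label = character(),
      benefit = numeric(), rank = integer(), best = logical(),
      no_deficiency = logical()
    ))
  }
  ind <- indicators[indicators$category == category & !is.na(indicators$value), ]
  deficit <- stats::setNames(1 - ind$value, ind$function_id)
  benefit <- vapply(cand$practice_id, function(p) {
    eff <- practices$effectiveness
    eff <- eff[eff$practice_id == p & eff$function_id %in% names(deficit), ]
    if (nrow(eff) == 0) return(0)
    sum(eff$e * deficit[eff$function_id])
  }, numeric(1))
  ord <- order(-benefit, cand$practice_id)
  out <- tibble::tibble(
    category = category,
    practice_id = cand$practice_id[ord],
    label = cand$label[ord],
    benefit = unname(benefit[ord]),
    rank = seq_along(ord)
  )
  out$best <- out$rank == 1
  out$no_deficiency <- max(out$benefit) == 0
  out
}

#' Recommend the best practice per category for a field
#'
#' Evaluates the battery on the field's most recent year (age 0, or the
#' youngest available), substitutes VSA ratings where present, and ranks
#' practices per category with [recommend_category()]. The management
#' category is skipped: it is itself an aggregate of practices.
#'
#' @param records field table rows of one field.
#' @param battery `indicator_battery`.
#' @param practices practice catalogue.
#' @param use_vsa substitute VSA ratings where available.
#' @return tibble of ranked practices for every category present, with a
#'   `field_id` column.
#' @export
recommend_field <- function(records, battery = default_battery(),
                            practices = default_practices(),
                            use_vsa = TRUE) {
  ids <- unique(records$field_id)
  if (length(ids) != 1) {
    stop(input_error("recommend_field expects records of a single field"))
  }
  battery <- validate_battery(battery)
  recent <- records[records$year_age == min(records$year_age), , drop = FALSE]
  indicators <- evaluate_battery(battery, recent)
  if (use_vsa) indicators <- apply_vsa(indicators, recent, battery)
  cats <- setdiff(unique(indicators$category), "management")
  out <- purrr::list_rbind(lapply(cats, function(k) {
    recommend_category(indicators, k, practices,
                       land_use = recent$land_use[1],
                       soil_type = recent$soil_type[1])
  }))
  dplyr::bind_cols(tibble::tibble(field_id = rep(ids, nrow(out))), out)
}
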
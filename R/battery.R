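# Indicator battery: configuration of soil functions and their evaluation
# curves, keyed by soil type x land use strata.

indicator_categories <- function() {
  c("chemical", "physical", "biological", "environmental", "management")
}

#' Read an indicator battery from a YAML or JSON configuration
#'
#' The battery is the list of soil functions to evaluate. Each entry maps
#' one measured property (or categorical field property) onto the 0--1
#' indicator scale through an evaluation curve that may differ per
#' soil type x land use stratum; `"*"` acts as a wildcard stratum key and
#' the most specific matching entry wins. Entries may declare a `vsa_item`
#' whose in-field rating replaces the model-derived indicator when a
#' visual soil assessment is available.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON battery file.
#' @return validated `indicator_battery` object.
#' @seealso [default_battery()] for the illustrative battery shipped with
#'   the package, and `inst/extdata/battery-default.yaml` for the schema.
#' @export
read_battery <- function(path) {
  if (!file.exists(path)) {
    stop(config_error(sprintf("battery config not found: %s", path)))
  }
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$functions)) {
    stop(config_error(sprintf(
      "battery config %s must have a top-level 'functions' list", path
    )))
  }
  validate_battery(structure(
    list(functions = cfg$functions, source = path),
    class = "indicator_battery"
  ))
}

#' Default illustrative indicator battery
#'
#' The 22-function battery shipped with the package: 9 chemical, 8
#' physical, 2 biological, 2 environmental functions plus the management
#' sub-score. Curve parameters are illustrative defaults chosen to be
#' agronomically plausible for Dutch-style fields; they are *not* an
#' authoritative national calibration and every value can be overridden
#' via [read_battery()].
#'
#' @return validated `indicator_battery` object.
#' @export
default_battery <- function() {
  read_battery(system.file("extdata", "battery-default.yaml",
                           package = "soilscore", mustWork = TRUE))
}

#' Validate an indicator battery
#'
#' Enforces the structural rules at load time: unique function ids, known
#' categories, ordered curve anchors, lookup scores in \[0, 1\], and the
#' minimum-coverage rule that the chemical, physical and biological
#' aspects each contribute at least two functions. Errors name the
#' offending function and curve entry.
#'
#' @param battery an `indicator_battery` (or bare list of definitions).
#' @return the battery, invisibly augmented with defaults filled in.
#' @export
validate_battery <- function(battery) {
  defs <- if (inherits(battery, "indicator_battery")) {
    battery$functions
  } else {
    battery
  }
  if (length(defs) == 0) stop(config_error("battery has no functions"))

  ids <- vapply(defs, function(d) d$id %||% "", character(1))
  if (any(!nzchar(ids))) stop(config_error("every function needs an 'id'"))
  if (anyDuplicated(ids)) {
    stop(config_error(sprintf(
      "duplicate function id(s): %s",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    )))
  }

  defs <- lapply(defs, function(d) {
    if (is.null(d$category) || !(d$category %in% indicator_categories())) {
      stop(config_error(sprintf(
        "category must be one of %s",
        paste(indicator_categories(), collapse = "/")
      ), d$id))
    }
    if (is.null(d$property)) {
      stop(config_error("missing 'property'", d$id))
    }
    known <- c(soil_properties()$property, "groundwater_class", "soil_type",
               "land_use")
    if (!d$property %in% known) {
      stop(config_error(sprintf("unknown property '%s'", d$property), d$id))
    }
    if (is.null(d$curves) || length(d$curves) == 0) {
      stop(config_error("needs at least one curve entry", d$id))
    }
    d$curves <- lapply(seq_along(d$curves), function(j) {
      cv <- d$curves[[j]]
      cv$soil_type <- cv$soil_type %||% "*"
      cv$land_use <- cv$land_use %||% "*"
      where <- sprintf("curve %d (%s/%s)", j, cv$soil_type, cv$land_use)
      if (!cv$soil_type %in% c("*", soil_types()) ||
          !cv$land_use %in% c("*", land_uses())) {
        stop(config_error(sprintf("%s: unknown stratum key", where), d$id))
      }
      kind <- cv$kind %||% ""
      if (kind == "two_anchor") {
        a <- unlist(cv$anchors)
        if (length(a) != 3) {
          stop(config_error(sprintf(
            "%s: two_anchor needs anchors [x_zero, x_half, x_opt]", where
          ), d$id))
        }
        # raises a configuration error itself when the ordering is invalid
        eval_two_anchor(a[2], a[1], a[2], a[3], function_id = d$id)
      } else if (kind == "optimum_window") {
        a <- unlist(cv$anchors)
        if (length(a) != 4) {
          stop(config_error(sprintf(
            "%s: optimum_window needs anchors [low0, low1, high1, high0]",
            where
          ), d$id))
        }
        eval_optimum_window(a[2], a[1], a[2], a[3], a[4], function_id = d$id)
      } else if (kind == "lookup") {
        tab <- unlist(cv$table)
        if (length(tab) == 0) {
          stop(config_error(sprintf("%s: empty lookup table", where), d$id))
        }
        if (any(tab < 0 | tab > 1)) {
          stop(config_error(sprintf(
            "%s: lookup scores must lie in [0, 1]", where
          ), d$id))
        }
      } else {
        stop(config_error(sprintf(
          "%s: kind must be two_anchor, optimum_window or lookup", where
        ), d$id))
      }
      cv
    })
    d
  })

  counts <- table(vapply(defs, `[[`, character(1), "category"))
  for (aspect in c("chemical", "physical", "biological")) {
    if (is.na(counts[aspect]) || counts[aspect] < 2) {
      stop(config_error(sprintf(
        "minimum-coverage rule violated: the %s aspect needs >= 2 functions, found %d",
        aspect, if (is.na(counts[aspect])) 0L else counts[aspect]
      )))
    }
  }

  structure(
    list(functions = defs,
         source = if (inherits(battery, "indicator_battery")) {
           battery$source
         } else {
           "<in-memory>"
         }),
    class = "indicator_battery"
  )
}

#' @export
print.indicator_battery <- function(x, ...) {
  cats <- vapply(x$functions, `[[`, character(1), "category")
  cat(sprintf("<indicator_battery> %d soil functions (%s)\n",
              length(x$functions),
              paste(sprintf("%s: %d", names(table(cats)), table(cats)),
                    collapse = ", ")))
  invisible(x)
}

battery_categories <- function(battery) {
  stats::setNames(
    vapply(battery$functions, `[[`, character(1), "category"),
    vapply(battery$functions, `[[`, character(1), "id")
  )
}

# Most specific curve for a stratum: exact match beats single wildcard
# beats double wildcard; first entry wins ties.
resolve_curve <- function(defn, soil_type, land_use) {
  best <- NULL
  best_spec <- -1L
  for (cv in defn$curves) {
    st_ok <- cv$soil_type == "*" || cv$soil_type == soil_type
    lu_ok <- cv$land_use == "*" || cv$land_use == land_use
    if (!st_ok || !lu_ok) next
    spec <- (cv$soil_type != "*") + (cv$land_use != "*")
    if (spec > best_spec) {
      best <- cv
      best_spec <- spec
    }
  }
  if (is.null(best)) {
    stop(config_error(sprintf(
      "no evaluation curve for stratum %s/%s", soil_type, land_use
    ), defn$id))
  }
  best
}

apply_curve <- function(cv, x, function_id) {
  if (cv$kind == "two_anchor") {
    a <- unlist(cv$anchors)
    eval_two_anchor(as.numeric(x), a[1], a[2], a[3], function_id)
  } else if (cv$kind == "optimum_window") {
    a <- unlist(cv$anchors)
    eval_optimum_window(as.numeric(x), a[1], a[2], a[3], a[4], function_id)
  } else {
    eval_lookup(x, cv$table, default = cv$default, function_id = function_id)
  }
}

#' Evaluate one soil function over field-year records
#'
#' Selects the evaluation curve matching each record's soil type and land
#' use and applies it to the function's property. Records where the
#' property is missing yield a missing indicator value (never zero), so
#' they drop out of later aggregation instead of dragging scores down.
#'
#' @param defn one battery entry (element of `battery$functions`).
#' @param records validated field table (see [validate_field_table()]).
#' @return tibble with one row per record: `field_id`, `year_age`,
#'   `function_id`, `category`, `value`, `source`.
#' @export
evaluate_indicator <- function(defn, records) {
  n <- nrow(records)
  x <- if (defn$property %in% names(records)) {
    records[[defn$property]]
  } else {
    rep(NA, n)
  }
  value <- rep(NA_real_, n)
  strata <- paste(records$soil_type, records$land_use, sep = "\r")
  for (s in unique(strata)) {
    idx <- which(strata == s)
    cv <- resolve_curve(defn, records$soil_type[idx[1]],
                        records$land_use[idx[1]])
    value[idx] <- apply_curve(cv, x[idx], defn$id)
  }
  tibble::tibble(
    field_id = records$field_id,
    year_age = records$year_age,
    function_id = defn$id,
    category = defn$category,
    value = value,
    source = ifelse(
      is.na(value), NA_character_,
      if (identical(defn$category, "management")) "config" else "measured_curve"
    )
  )
}

#' Evaluate the full indicator battery over field-year records
#'
#' Applies [evaluate_indicator()] for every configured soil function,
#' returning the long indicator table that feeds aggregation, VSA
#' substitution, recommendations and diagnostics.
#'
#' @param battery `indicator_battery`.
#' @param records validated field table.
#' @return long tibble of indicator values (`field_id`, `year_age`,
#'   `function_id`, `category`, `value`, `source`).
#' @export
evaluate_battery <- function(battery, records) {
  battery <- validate_battery(battery)
  purrr::list_rbind(lapply(battery$functions, evaluate_indicator, records))
}
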
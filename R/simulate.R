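# Reproducible generator of multi-year synthetic field records:
# truncated-normal soil properties per soil type, a persistent land-use
# rotation chain, property-linked VSA ratings, and good/poor field pairs.

rtrunc_norm <- function(n, mean, sd, lower, upper) {
  if (sd <= 0) return(rep(pmin(pmax(mean, lower), upper), n))
  p <- stats::runif(n, stats::pnorm(lower, mean, sd),
                    stats::pnorm(upper, mean, sd))
  pmin(pmax(stats::qnorm(p, mean, sd), lower), upper)
}

#' Per-soil-type property distributions of the synthetic generator
#'
#' Truncated-normal parameters (mean, sd, truncation bounds) for every
#' measured property, per soil type. Values are illustrative defaults in
#' the range of Dutch-style agricultural topsoils.
#'
#' @return tibble with columns `soil_type`, `property`, `mean`, `sd`,
#'   `lower`, `upper`.
#' @export
default_property_params <- function() {
  per_type <- function(property, sand, clay, loess, peat, lower, upper) {
    tibble::tibble(
      soil_type = soil_types(), property = property,
      mean = c(sand[1], clay[1], loess[1], peat[1]),
      sd = c(sand[2], clay[2], loess[2], peat[2]),
      lower = lower, upper = upper
    )
  }
  dplyr::bind_rows(
    per_type("organic_matter", c(4, 1.5), c(3.5, 1.2), c(2.5, 0.8),
             c(20, 6), 0.5, 60),
    per_type("ph", c(5.4, 0.5), c(6.8, 0.5), c(6.5, 0.4), c(5.0, 0.4),
             3.5, 8.5),
    per_type("clay", c(4, 2), c(30, 8), c(15, 4), c(15, 6), 1, 60),
    per_type("silt", c(12, 5), c(40, 8), c(60, 8), c(30, 8), 2, 80),
    per_type("n_total", c(1500, 400), c(1800, 400), c(1200, 300),
             c(8000, 2000), 200, 30000),
    per_type("p_avail", c(3.5, 1.5), c(3.5, 1.5), c(3.5, 1.5), c(4, 1.5),
             0.2, 15),
    per_type("k_avail", c(100, 40), c(120, 40), c(100, 40), c(110, 40),
             10, 400),
    per_type("mg_avail", c(80, 30), c(120, 40), c(100, 35), c(150, 50),
             5, 500),
    per_type("cu_avail", c(5, 2), c(5, 2), c(5, 2), c(5, 2), 0.2, 30),
    per_type("s_avail", c(20, 8), c(20, 8), c(20, 8), c(35, 12), 2, 100),
    per_type("zn_avail", c(5, 2), c(5, 2), c(5, 2), c(5, 2), 0.2, 40),
    per_type("cec", c(60, 20), c(200, 50), c(120, 30), c(250, 60), 10, 500),
    per_type("cec_occ_ca", c(85, 5), c(85, 5), c(85, 5), c(80, 6), 50, 98),
    per_type("cec_occ_mg", c(8, 3), c(8, 3), c(8, 3), c(10, 3), 1, 30),
    per_type("cec_occ_k", c(3, 1.5), c(3, 1.5), c(3, 1.5), c(3, 1.5),
             0.5, 15),
    per_type("pmn", c(60, 25), c(80, 30), c(50, 20), c(150, 50), 2, 500),
    per_type("bulk_density", c(1.45, 0.10), c(1.30, 0.12), c(1.40, 0.10),
             c(0.80, 0.15), 0.4, 1.9),
    per_type("management_score", c(0.65, 0.15), c(0.65, 0.15),
             c(0.65, 0.15), c(0.65, 0.15), 0, 1)
  )
}

#' Synthetic-data generator configuration
#'
#' Defaults emulate the structure of Dutch-style multi-year field
#' records: 10-year records, a sand-dominated soil-type mix, a
#' grassland-heavy land-use mix with persistent rotations, lab-style
#' between-year noise (CV 3%), and a VSA on half the fields.
#'
#' @param n_fields number of fields to generate.
#' @param years record length per field (<= 10).
#' @param seed optional RNG seed for reproducibility.
#' @param soil_type_mix named proportions over [soil_types()], sum 1.
#' @param land_use_mix named proportions over [land_uses()], sum 1.
#' @param persistence probability of keeping last year's land use in the
#'   rotation chain (the chain's stationary mix stays `land_use_mix`).
#' @param vsa_fraction share of fields receiving a VSA (most recent year).
#' @param year_cv multiplicative between-year coefficient of variation of
#'   the property values (pH varies additively, sd `0.1`).
#' @param vsa_noise probability that a VSA item rating is shifted one
#'   level away from its property-implied value.
#' @param pair_offset latent quality shift used by [generate_pairs()]:
#'   relative reduction of the poor member's organic matter and PMN, and
#'   `0.4 * pair_offset` relative increase of its bulk density.
#' @param property_params distribution table, see
#'   [default_property_params()].
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_fields = 100, years = 10, seed = NULL,
                              soil_type_mix = c(sand = 0.50, clay = 0.33,
                                                loess = 0.05, peat = 0.12),
                              land_use_mix = c(grassland = 0.50,
                                               maize = 0.15, arable = 0.35),
                              persistence = 0.8, vsa_fraction = 0.5,
                              year_cv = 0.03, vsa_noise = 0.15,
                              pair_offset = 0.15,
                              property_params = default_property_params()) {
  check_mix <- function(mix, levels, what) {
    if (is.null(names(mix)) || !all(names(mix) %in% levels) ||
        any(mix < 0) || abs(sum(mix) - 1) > 1e-6) {
      stop(config_error(sprintf(
        "%s must be named non-negative proportions over {%s} summing to 1",
        what, paste(levels, collapse = ", ")
      )))
    }
  }
  check_mix(soil_type_mix, soil_types(), "soil_type_mix")
  check_mix(land_use_mix, land_uses(), "land_use_mix")
  if (n_fields < 1 || years < 1 || years > 10) {
    stop(config_error("need n_fields >= 1 and years in [1, 10]"))
  }
  if (persistence < 0 || persistence > 1 ||
      vsa_fraction < 0 || vsa_fraction > 1 ||
      pair_offset < 0 || pair_offset > 1) {
    stop(config_error(
      "persistence, vsa_fraction and pair_offset must lie in [0, 1]"
    ))
  }
  if (any(property_params$sd < 0)) {
    stop(config_error("property sds must be >= 0"))
  }
  structure(
    list(n_fields = n_fields, years = years, seed = seed,
         soil_type_mix = soil_type_mix, land_use_mix = land_use_mix,
         persistence = persistence, vsa_fraction = vsa_fraction,
         year_cv = year_cv, vsa_noise = vsa_noise,
         pair_offset = pair_offset, property_params = property_params),
    class = "simulation_config"
  )
}

#' Generate a persistent land-use rotation
#'
#' Markov chain over land uses: each year keeps the previous land use
#' with probability `persistence` and otherwise redraws from
#' `land_use_mix`, so the stationary distribution equals the mix. The
#' sequence is returned oldest-first.
#'
#' @param years sequence length, >= 1.
#' @param land_use_mix named proportions over [land_uses()].
#' @param persistence stay probability in \[0, 1\].
#' @param seed optional RNG seed.
#' @return character vector of length `years`.
#' @export
generate_rotation <- function(years, land_use_mix = c(grassland = 0.5,
                                                      maize = 0.15,
                                                      arable = 0.35),
                              persistence = 0.8, seed = NULL) {
  if (years < 1) stop(input_error("years must be >= 1"))
  if (is.null(names(land_use_mix)) || any(land_use_mix < 0) ||
      sum(land_use_mix) <= 0) {
    stop(config_error("degenerate land_use_mix"))
  }
  if (!is.null(seed)) set.seed(seed)
  mix <- land_use_mix / sum(land_use_mix)
  seq_out <- character(years)
  seq_out[1] <- sample(names(mix), 1, prob = mix)
  for (t in seq_len(years)[-1]) {
    seq_out[t] <- if (stats::runif(1) < persistence) {
      seq_out[t - 1]
    } else {
      sample(names(mix), 1, prob = mix)
    }
  }
  seq_out
}

gw_class_probs <- function(soil_type) {
  probs <- list(
    sand  = c(0, 0.05, 0.10, 0.15, 0.20, 0.30, 0.15, 0.05),
    clay  = c(0.05, 0.15, 0.25, 0.25, 0.15, 0.10, 0.05, 0),
    loess = c(0, 0, 0, 0.05, 0.10, 0.25, 0.35, 0.25),
    peat  = c(0.25, 0.35, 0.25, 0.10, 0.05, 0, 0, 0)
  )
  probs[[soil_type]]
}

draw_crop_code <- function(land_use) {
  arable_crops <- c("potato", "winter_wheat", "sugar_beet", "barley", "onion")
  vapply(land_use, function(lu) {
    switch(lu,
           grassland = "grass_permanent",
           maize = "maize_silage",
           sample(arable_crops, 1))
  }, character(1), USE.NAMES = FALSE)
}

# One base (field-level) draw per property; texture closed to 100%.
draw_base_properties <- function(soil_type, cfg) {
  n <- length(soil_type)
  params <- cfg$property_params
  out <- tibble::tibble(.rows = n)
  for (p in unique(params$property)) {
    x <- numeric(n)
    for (st in unique(soil_type)) {
      idx <- which(soil_type == st)
      pr <- params[params$property == p & params$soil_type == st, ]
      if (nrow(pr) != 1) {
        stop(config_error(sprintf(
          "property_params must have one row for %s x %s", p, st
        )))
      }
      x[idx] <- rtrunc_norm(length(idx), pr$mean, pr$sd, pr$lower, pr$upper)
    }
    out[[p]] <- x
  }
  # close texture: redraw rows where clay + silt leaves no room for sand
  for (attempt in seq_len(100)) {
    over <- out$clay + out$silt > 97
    if (!any(over)) break
    for (st in unique(soil_type[over])) {
      idx <- which(over & soil_type == st)
      for (p in c("clay", "silt")) {
        pr <- params[params$property == p & params$soil_type == st, ]
        out[[p]][idx] <- rtrunc_norm(length(idx), pr$mean, pr$sd,
                                     pr$lower, pr$upper)
      }
    }
  }
  out$sand <- 100 - out$clay - out$silt
  out
}

rating_from_breaks <- function(x, poor_below, good_above) {
  ifelse(x < poor_below, "poor",
         ifelse(x >= good_above, "good", "moderate"))
}

add_rating_noise <- function(rating, prob) {
  levels <- vsa_ratings()
  n <- length(rating)
  shift <- stats::runif(n) < prob
  step <- sample(c(-1L, 1L), n, replace = TRUE)
  idx <- match(rating, levels)
  idx[shift] <- pmin(pmax(idx[shift] + step[shift], 1L), 3L)
  levels[idx]
}

# Property-linked VSA ratings for year-0 rows, plus rating noise.
generate_vsa <- function(rows, cfg) {
  bd_breaks <- list(sand = c(1.60, 1.45), clay = c(1.50, 1.35),
                    loess = c(1.60, 1.45), peat = c(1.10, 0.90))
  bd_poor <- vapply(rows$soil_type, function(s) bd_breaks[[s]][1], numeric(1))
  bd_good <- vapply(rows$soil_type, function(s) bd_breaks[[s]][2], numeric(1))
  gw <- match(rows$groundwater_class, groundwater_classes())
  out <- tibble::tibble(
    vsa_earthworms = rating_from_breaks(rows$pmn, 30, 80),
    # bulk density: lower is better, so flip the comparison
    vsa_compaction = ifelse(rows$bulk_density >= bd_poor, "poor",
                            ifelse(rows$bulk_density < bd_good,
                                   "good", "moderate")),
    vsa_gray_spots = rating_from_breaks(gw, 3, 5),
    vsa_ponding = rating_from_breaks(gw, 2, 4),
    vsa_cracks = ifelse(rows$clay > 35 & rows$organic_matter < 3,
                        "moderate", "good"),
    vsa_bio_pores = rating_from_breaks(rows$pmn, 25, 70),
    vsa_rooting_depth = ifelse(rows$bulk_density >= bd_poor + 0.05, "poor",
                               ifelse(rows$bulk_density < bd_good + 0.05,
                                      "good", "moderate")),
    vsa_structure = rating_from_breaks(rows$organic_matter, 2, 3.5),
    vsa_crop_cover = sample(vsa_ratings(), nrow(rows), replace = TRUE,
                            prob = c(0.1, 0.3, 0.6))
  )
  for (col in names(out)) out[[col]] <- add_rating_noise(out[[col]], cfg$vsa_noise)
  out
}

# Expand field-level base draws into per-year rows with lab-style noise.
expand_years <- function(base, field_id, soil_type, gw_class, rotation_list,
                         cfg) {
  n <- nrow(base)
  y <- cfg$years
  idx <- rep(seq_len(n), each = y)
  params <- cfg$property_params
  rows <- tibble::tibble(
    field_id = field_id[idx],
    year_age = rep(seq(y - 1, 0), times = n),
    soil_type = soil_type[idx],
    land_use = unlist(rotation_list),
    groundwater_class = gw_class[idx]
  )
  rows$crop_code <- draw_crop_code(rows$land_use)
  for (p in unique(params$property)) {
    v <- base[[p]][idx]
    if (p == "management_score") {
      # management evaluation is a per-field score, constant over the record
    } else if (p == "ph") {
      v <- v + stats::rnorm(length(v), 0, 0.1)
    } else if (!p %in% c("clay", "silt", "sand")) {
      v <- v * (1 + stats::rnorm(length(v), 0, cfg$year_cv))
    }
    lo <- min(params$lower[params$property == p])
    hi <- max(params$upper[params$property == p])
    rows[[p]] <- pmin(pmax(v, lo), hi)
  }
  rows$sand <- base$sand[idx]  # texture fixed within a field's record
  rows$clay <- base$clay[idx]
  rows$silt <- base$silt[idx]
  rows
}

#' Generate synthetic multi-year field records
#'
#' Draws `n_fields` fields: a soil type from the configured mix, a
#' groundwater class plausible for that soil type, one truncated-normal
#' base draw per property, a persistent land-use rotation, per-year
#' lab-style noise on the property values, and (for `vsa_fraction` of
#' the fields) a property-linked VSA on the most recent year.
#' Deterministic given `cfg$seed`; the output always passes
#' [validate_field_table()].
#'
#' @param cfg [simulation_config()].
#' @return field table tibble, `n_fields * years` rows.
#' @export
generate_fields <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_fields
  field_id <- sprintf("F%05d", seq_len(n))
  soil_type <- sample(names(cfg$soil_type_mix), n, replace = TRUE,
                      prob = cfg$soil_type_mix)
  gw_class <- vapply(soil_type, function(st) {
    sample(groundwater_classes(), 1, prob = gw_class_probs(st))
  }, character(1), USE.NAMES = FALSE)
  base <- draw_base_properties(soil_type, cfg)
  rotations <- lapply(seq_len(n), function(i) {
    generate_rotation(cfg$years, cfg$land_use_mix, cfg$persistence)
  })
  rows <- expand_years(base, field_id, soil_type, gw_class, rotations, cfg)

  for (col in vsa_columns()) rows[[col]] <- NA_character_
  with_vsa <- field_id[stats::runif(n) < cfg$vsa_fraction]
  target <- rows$field_id %in% with_vsa & rows$year_age == 0
  if (any(target)) {
    rows[target, vsa_columns()] <- generate_vsa(rows[target, ], cfg)
  }
  validate_field_table(rows)$records
}

#' Generate paired good/poor fields
#'
#' Emulates farmer-selected field pairs: both members of a pair share
#' the same region (soil type, groundwater class), rotation and
#' management, and one field-level base property draw. Each member then
#' receives independent between-year noise; the "poor" member's
#' biologically and physically linked properties are shifted toward
#' deficiency (organic matter and PMN scaled by `1 - pair_offset`, bulk
#' density by `1 + 0.4 * pair_offset`). Both members carry a complete
#' VSA derived from their own (shifted) properties, so the VSA
#' substitution path is exercised end to end. With `pair_offset = 0` the
#' two members are statistically exchangeable.
#'
#' @param n_pairs number of pairs, >= 1.
#' @param pair_offset shift in \[0, 1\]; overrides `cfg$pair_offset`.
#' @param seed optional RNG seed.
#' @param cfg [simulation_config()].
#' @return list with field tables `good` and `poor` (`n_pairs * years`
#'   rows each); members of pair `k` are named `P<k>_good` / `P<k>_poor`.
#' @export
generate_pairs <- function(n_pairs = 11, pair_offset = NULL, seed = NULL,
                           cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (n_pairs < 1) stop(input_error("n_pairs must be >= 1"))
  offset <- pair_offset %||% cfg$pair_offset
  if (offset < 0 || offset > 1) {
    stop(config_error("pair_offset must lie in [0, 1]"))
  }
  if (!is.null(seed)) set.seed(seed)

  soil_type <- sample(names(cfg$soil_type_mix), n_pairs, replace = TRUE,
                      prob = cfg$soil_type_mix)
  gw_class <- vapply(soil_type, function(st) {
    sample(groundwater_classes(), 1, prob = gw_class_probs(st))
  }, character(1), USE.NAMES = FALSE)
  base_good <- draw_base_properties(soil_type, cfg)
  base_poor <- base_good
  params <- cfg$property_params
  clamp <- function(p, v) {
    pmin(pmax(v, min(params$lower[params$property == p])),
         max(params$upper[params$property == p]))
  }
  base_poor$organic_matter <- clamp("organic_matter",
                                    base_good$organic_matter * (1 - offset))
  base_poor$pmn <- clamp("pmn", base_good$pmn * (1 - offset))
  base_poor$bulk_density <- clamp("bulk_density",
                                  base_good$bulk_density * (1 + 0.4 * offset))

  rotations <- lapply(seq_len(n_pairs), function(i) {
    generate_rotation(cfg$years, cfg$land_use_mix, cfg$persistence)
  })
  member <- function(base, suffix) {
    ids <- sprintf("P%02d_%s", seq_len(n_pairs), suffix)
    rows <- expand_years(base, ids, soil_type, gw_class, rotations, cfg)
    for (col in vsa_columns()) rows[[col]] <- NA_character_
    target <- rows$year_age == 0
    rows[target, vsa_columns()] <- generate_vsa(rows[target, ], cfg)
    validate_field_table(rows)$records
  }
  list(good = member(base_good, "good"), poor = member(base_poor, "poor"))
}
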
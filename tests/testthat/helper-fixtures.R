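# Fixtures built in code: a complete single-field record and small
# purpose-built batteries.

# One complete field-year record (all properties present, mid-range
# values for a sandy arable field); overridable per column.
make_field <- function(field_id = "T1", years = 1, soil_type = "sand",
                       land_use = "arable", gw = "VI", ...) {
  overrides <- list(...)
  df <- tibble::tibble(
    field_id = field_id,
    year_age = seq_len(years) - 1L,
    soil_type = soil_type,
    land_use = land_use,
    groundwater_class = gw,
    crop_code = "potato",
    organic_matter = 4, ph = 5.8, clay = 4, silt = 12, sand = 84,
    n_total = 1500, p_avail = 3.5, k_avail = 100, mg_avail = 80,
    cu_avail = 5, s_avail = 20, zn_avail = 5, cec = 60,
    cec_occ_ca = 85, cec_occ_mg = 8, cec_occ_k = 3, pmn = 60,
    bulk_density = 1.45, management_score = 0.65
  )
  for (nm in names(overrides)) df[[nm]] <- overrides[[nm]]
  df
}

add_vsa <- function(df, rating = "good", ...) {
  overrides <- list(...)
  for (col in paste0("vsa_", vsa_items())) df[[col]] <- rating
  for (nm in names(overrides)) df[[paste0("vsa_", nm)]] <- overrides[[nm]]
  df
}

# Minimal battery satisfying the coverage rule: two functions each for
# chemical / physical / biological, simple wildcard curves.
mini_battery <- function() {
  validate_battery(list(
    list(id = "c1", category = "chemical", property = "n_total",
         curves = list(list(kind = "two_anchor", anchors = c(0, 1000, 2000)))),
    list(id = "c2", category = "chemical", property = "ph",
         curves = list(list(kind = "optimum_window",
                            anchors = c(4.5, 5.5, 6.5, 7.5)))),
    list(id = "p1", category = "physical", property = "bulk_density",
         curves = list(list(kind = "two_anchor", anchors = c(1.8, 1.5, 1.2)))),
    list(id = "p2", category = "physical", property = "groundwater_class",
         curves = list(list(kind = "lookup",
                            table = list(V = 0.4, VI = 0.6, VII = 0.8)))),
    list(id = "b1", category = "biological", property = "pmn",
         curves = list(list(kind = "two_anchor", anchors = c(0, 50, 100)))),
    list(id = "b2", category = "biological", property = "organic_matter",
         curves = list(list(kind = "two_anchor", anchors = c(0, 2, 5))))
  ))
}

# Battery whose every indicator equals the record's management_score:
# the identity curve (0, 0.5, 1) on a 0-1 property. Category sizes
# mirror the default 22-function battery, so a record with
# management_score = v yields the constant indicator vector v.
identity_battery <- function() {
  counts <- c(chemical = 9, physical = 8, biological = 2,
              environmental = 2, management = 1)
  defs <- unlist(lapply(names(counts), function(cat) {
    lapply(seq_len(counts[[cat]]), function(i) {
      list(id = sprintf("id_%s_%d", cat, i), category = cat,
           property = "management_score",
           curves = list(list(kind = "two_anchor", anchors = c(0, 0.5, 1))))
    })
  }), recursive = FALSE)
  validate_battery(defs)
}

# Step-by-step recomputation of the three aggregation steps for one
# field, used as the independent oracle against score_fields().
manual_score <- function(indicators, cfg = aggregation_config()) {
  fields <- unique(indicators$field_id)
  purrr::list_rbind(lapply(fields, function(fid) {
    ind <- indicators[indicators$field_id == fid, ]
    cats <- unique(ind$category)
    ages <- sort(unique(ind$year_age))
    s_k <- vapply(cats, function(k) {
      per_year <- vapply(ages, function(a) {
        aggregate_within_category(
          ind$value[ind$category == k & ind$year_age == a], c = cfg$c
        )
      }, numeric(1))
      aggregate_years(per_year, ages, cfg)
    }, numeric(1))
    n_k <- vapply(cats, function(k) {
      sub <- ind[ind$category == k & !is.na(ind$value), ]
      length(unique(sub$function_id))
    }, integer(1))
    names(s_k) <- names(n_k) <- cats
    tibble::tibble(
      field_id = fid,
      final_score = aggregate_categories(s_k, n_k, cfg)
    )
  }))
}
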
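test_that("default battery has the expected category composition", {
  battery <- default_battery()
  cats <- table(vapply(battery$functions, `[[`, character(1), "category"))
  expect_equal(length(battery$functions), 22)
  expect_equal(as.vector(cats[c("chemical", "physical", "biological",
                                "environmental", "management")]),
               c(9L, 8L, 2L, 2L, 1L))
})

test_that("a complete record evaluates every function; management comes from config", {
  ind <- evaluate_battery(default_battery(), make_field())
  expect_equal(nrow(ind), 22)
  expect_true(all(!is.na(ind$value)))
  expect_true(all(ind$value >= 0 & ind$value <= 1))
  expect_equal(ind$source[ind$function_id == "i_m_management"], "config")
  expect_equal(ind$value[ind$function_id == "i_m_management"], 0.65)
  expect_true(all(ind$source[ind$category != "management"] ==
                    "measured_curve"))
})

test_that("missing properties give missing indicators, never zero, independently", {
  rec <- make_field(pmn = NA_real_, organic_matter = NA_real_)
  ind <- evaluate_battery(default_battery(), rec)
  bio <- ind[ind$category == "biological", ]
  expect_true(all(is.na(bio$value)))
  # unaffected functions keep their values
  full <- evaluate_battery(default_battery(), make_field())
  others <- setdiff(full$function_id[!is.na(ind$value)], bio$function_id)
  expect_equal(ind$value[match(others, ind$function_id)],
               full$value[match(others, full$function_id)])
})

test_that("downsized 10-parameter profile evaluates exactly the satisfiable functions", {
  # common worldwide profile: total N, available P, available K, CEC, pH,
  # clay, silt, sand, organic matter, bulk density
  rec <- make_field(
    mg_avail = NA_real_, cu_avail = NA_real_, s_avail = NA_real_,
    zn_avail = NA_real_, cec_occ_ca = NA_real_, cec_occ_mg = NA_real_,
    cec_occ_k = NA_real_, pmn = NA_real_, management_score = NA_real_,
    gw = NA_character_
  )
  ind <- evaluate_battery(default_battery(), rec)
  # oracle: a function is evaluable iff its property survives downsizing
  available <- c("n_total", "p_avail", "k_avail", "cec", "ph", "clay",
                 "silt", "sand", "organic_matter", "bulk_density")
  battery <- default_battery()
  expected <- vapply(battery$functions, function(d) {
    d$property %in% available
  }, logical(1))
  names(expected) <- vapply(battery$functions, `[[`, character(1), "id")
  expect_equal(!is.na(ind$value[match(names(expected), ind$function_id)]),
               unname(expected))
})

test_that("indicator value equals the curve primitive applied to the raw property", {
  rec <- make_field()
  battery <- default_battery()
  for (fid in c("i_c_p", "i_p_compaction", "i_c_ph", "i_p_drought")) {
    defn <- battery$functions[[which(vapply(battery$functions, `[[`,
                                            character(1), "id") == fid)]]
    got <- evaluate_indicator(defn, rec)$value
    cv <- defn$curves[[length(defn$curves)]]  # wildcard entry for sand/arable
    x <- rec[[defn$property]]
    manual <- if (cv$kind == "two_anchor") {
      a <- unlist(cv$anchors)
      eval_two_anchor(x, a[1], a[2], a[3])
    } else if (cv$kind == "optimum_window") {
      a <- unlist(cv$anchors)
      eval_optimum_window(x, a[1], a[2], a[3], a[4])
    } else {
      eval_lookup(x, cv$table, default = cv$default)
    }
    expect_equal(got, manual, info = fid)
  }
})

test_that("the most specific stratum curve wins and absent strata error", {
  defs <- list(
    list(id = "f1", category = "chemical", property = "n_total",
         curves = list(
           list(kind = "two_anchor", anchors = c(0, 1000, 2000)),
           list(soil_type = "sand", land_use = "arable",
                kind = "two_anchor", anchors = c(0, 500, 1000))
         ))
  )
  battery <- c(defs, mini_battery()$functions[2:6])
  rec <- make_field(n_total = 1000)  # sand/arable
  ind <- evaluate_battery(battery, rec)
  # exact sand/arable curve saturates at 1000, wildcard would give 0.5
  expect_equal(ind$value[ind$function_id == "f1"], 1.0)
  expect_equal(evaluate_battery(battery,
                                make_field(soil_type = "clay", clay = 30,
                                           silt = 40, sand = 30,
                                           n_total = 1000))$value[1], 0.5)
})

test_that("missing stratum curve raises a configuration error naming the stratum", {
  defs <- c(
    list(list(id = "only_clay", category = "chemical", property = "ph",
              curves = list(list(soil_type = "clay", kind = "optimum_window",
                                 anchors = c(4.5, 5.5, 6.5, 7.5))))),
    mini_battery()$functions
  )
  expect_error(evaluate_battery(defs, make_field()),
               class = "soilscore_config_error")
  expect_error(evaluate_battery(defs, make_field()), regexp = "sand/arable")
})

test_that("battery validation enforces ids, coverage and curve sanity", {
  dup <- mini_battery()$functions
  dup[[2]]$id <- "c1"
  expect_error(validate_battery(dup), class = "soilscore_config_error")
  expect_error(validate_battery(dup), regexp = "duplicate")

  thin <- mini_battery()$functions[-5]  # only one biological function left
  expect_error(validate_battery(thin),
               class = "soilscore_config_error")

  bad <- mini_battery()$functions
  bad[[1]]$curves[[1]]$anchors <- c(5, 5, 10)
  expect_error(validate_battery(bad), class = "soilscore_config_error")
})

test_that("battery round-trips through YAML and evaluation is order-independent", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(functions = mini_battery()$functions), path)
  battery <- read_battery(path)
  rec <- make_field()
  a <- evaluate_battery(battery, rec)
  shuffled <- battery
  shuffled$functions <- rev(shuffled$functions)
  b <- evaluate_battery(shuffled, rec)
  expect_equal(a[order(a$function_id), ], b[order(b$function_id), ])
})
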
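test_that("distance-to-target weight follows 1/(I + c)", {
  expect_equal(weight_distance_to_target(0.2, 0.2), 2.5)
  expect_equal(weight_distance_to_target(1.0, 0.2), 1 / 1.2)
  w <- weight_distance_to_target(c(0, 0.5, 1), 0.37)
  expect_true(all(diff(w) < 0))
  expect_error(weight_distance_to_target(0.5, c = 0),
               class = "soilscore_config_error")
})

test_that("within-category aggregation matches hand arithmetic and is idempotent", {
  # (2.5 * 0.2 + (1/1.2) * 1.0) / (2.5 + 1/1.2) = 0.4
  expect_equal(aggregate_within_category(c(0.2, 1.0), c = 0.2), 0.4,
               tolerance = 1e-12)
  for (v in c(0, 0.31, 0.5, 1)) {
    expect_equal(aggregate_within_category(rep(v, 3)), v, tolerance = 1e-12)
  }
  expect_true(is.na(aggregate_within_category(c(NA_real_, NA_real_))))
})

test_that("limiting-factor weighting never exceeds the arithmetic mean", {
  set.seed(7)
  for (i in 1:1000) {
    v <- stats::runif(sample(2:10, 1))
    agg <- aggregate_within_category(v)
    expect_lte(agg, mean(v) + 1e-12)
    if (diff(range(v)) > 1e-9) {
      expect_lt(agg, mean(v))
    } else {
      expect_equal(agg, mean(v), tolerance = 1e-9)
    }
    expect_gte(agg, min(v) - 1e-12)
  }
})

test_that("year aggregation weights recent crops double and renormalizes", {
  # (5 years * 1.0 * 1 + 5 years * 0.5 * 0) / 7.5
  expect_equal(aggregate_years(c(rep(1, 5), rep(0, 5)), 0:9), 5 / 7.5,
               tolerance = 1e-12)
  expect_equal(round(aggregate_years(c(rep(1, 5), rep(0, 5)), 0:9), 4),
               0.6667)
  expect_equal(aggregate_years(rep(0.42, 10), 0:9), 0.42)
  expect_equal(aggregate_years(0.7, 0), 0.7)
  # missing years are excluded, weights renormalize
  expect_equal(aggregate_years(c(0.8, NA, 0.4), c(0, 4, 7)),
               aggregate_years(c(0.8, 0.4), c(0, 7)))
})

test_that("category weight is log2(n + 1), zero only for empty categories", {
  cfg <- aggregation_config()
  expect_equal(weight_category(1, cfg), 1.0)
  expect_equal(weight_category(0, cfg), 0.0)
  expect_equal(weight_category(9, cfg), log2(10))
  expect_equal(round(weight_category(9, cfg), 4), 3.3219)
  expect_error(weight_category(-1, cfg), class = "soilscore_input_error")
})

test_that("category aggregation matches the hand-computed example", {
  s <- c(chemical = 0.8, physical = 0.6, biological = 0.9,
         environmental = 0.7)
  n <- c(9, 8, 2, 2)
  # spreadsheet-style recomputation with log2(n + 1) weights
  w <- log2(n + 1)
  expected <- sum(w * s) / sum(w)
  got <- aggregate_categories(s, n)
  expect_equal(got, expected, tolerance = 1e-12)
  expect_equal(round(got, 4), 0.7344)
  expect_equal(aggregate_categories(rep(0.55, 4), c(3, 1, 7, 2)), 0.55)
  set.seed(11)
  for (i in 1:200) {
    sv <- stats::runif(5)
    nv <- sample(1:9, 5, replace = TRUE)
    f <- aggregate_categories(sv, nv)
    expect_gte(f, min(sv) - 1e-12)
    expect_lte(f, max(sv) + 1e-12)
  }
})

test_that("management can be excluded from the final score", {
  s <- c(chemical = 0.8, physical = 0.6, biological = 0.9,
         environmental = 0.7, management = 0.1)
  n <- c(9, 8, 2, 2, 1)
  with_m <- aggregate_categories(s, n, aggregation_config())
  without_m <- aggregate_categories(
    s, n, aggregation_config(include_management = FALSE)
  )
  expect_equal(without_m, aggregate_categories(s[1:4], n[1:4]))
  expect_gt(without_m, with_m)
  expect_error(
    aggregate_categories(c(management = 0.5), 1,
                         aggregation_config(include_management = FALSE)),
    class = "soilscore_input_error"
  )
})

test_that("score_field equals the step-by-step composition of the three steps", {
  cfg <- simulation_config(n_fields = 20, seed = 202)
  records <- generate_fields(cfg)
  battery <- default_battery()
  acfg <- aggregation_config()
  ind <- apply_vsa(evaluate_battery(battery, records), records, battery)
  oracle <- manual_score(ind, acfg)
  got <- score_fields(records, battery, acfg)
  merged <- dplyr::left_join(oracle, got, by = "field_id",
                             suffix = c("_manual", ""))
  expect_equal(merged$final_score, merged$final_score_manual,
               tolerance = 1e-12)
})

test_that("a field with every indicator at 1 scores exactly 1 (class good)", {
  rec <- make_field(years = 10, management_score = 1)
  report <- score_field(rec, identity_battery())
  expect_equal(report$final_score, 1, tolerance = 1e-12)
  expect_equal(report$class, "good")
})

test_that("single-year fields make the year step an identity", {
  rec <- make_field(years = 1)
  report <- score_field(rec, default_battery())
  per_year <- report$per_year[order(report$per_year$category), ]
  per_cat <- report$category_scores[order(report$category_scores$category), ]
  expect_equal(per_year$score, per_cat$score, tolerance = 1e-12)
})

test_that("score_field rejects mixed field ids and records its weights", {
  two <- dplyr::bind_rows(make_field("A"), make_field("B"))
  expect_error(score_field(two), class = "soilscore_input_error")
  report <- score_field(make_field(years = 10))
  expect_equal(report$weights$distance_to_target_offset, 0.2)
  expect_equal(report$weights$year$weight, c(rep(1, 5), rep(0.5, 5)))
  expect_true(all(c("n_k", "weight") %in% names(report$weights$category)))
  # final score bounded by the category sub-scores
  expect_gte(report$final_score, min(report$category_scores$score))
  expect_lte(report$final_score, max(report$category_scores$score))
})

test_that("score report serializes to nested JSON", {
  report <- score_field(make_field(years = 2))
  parsed <- jsonlite::fromJSON(as_json(report))
  expect_equal(parsed$field_id, "T1")
  expect_equal(parsed$final_score, report$final_score)
  expect_equal(nrow(parsed$category_scores), 5)
})
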
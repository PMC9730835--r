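test_that("VSA item scores map the three-level scale onto {0, 0.5, 1}", {
  expect_equal(vsa_item_score(c("good", "moderate", "poor")), c(1, 0.5, 0))
  expect_error(vsa_item_score("excellent"), class = "soilscore_input_error")
})

test_that("overall VSA score is the mean of the nine items", {
  all_good <- stats::setNames(rep("good", 9), vsa_items())
  expect_equal(vsa_overall(all_good), 1)
  mixed <- stats::setNames(c(rep("good", 5), rep("poor", 4)), vsa_items())
  expect_equal(vsa_overall(mixed), 5 / 9)
  expect_equal(vsa_overall(stats::setNames(rep("moderate", 9), vsa_items())),
               0.5)
  expect_error(vsa_overall(all_good[-1]), class = "soilscore_input_error")
  expect_equal(vsa_overall(add_vsa(make_field(), "moderate")), 0.5)
})

test_that("apply_vsa replaces exactly the compaction and structure-linked indicators", {
  battery <- default_battery()
  rec_plain <- make_field()
  ind_plain <- evaluate_battery(battery, rec_plain)
  expect_equal(apply_vsa(ind_plain, rec_plain, battery), ind_plain)

  rec <- add_vsa(make_field(), "good", compaction = "poor",
                 structure = "moderate")
  ind <- evaluate_battery(battery, rec)
  sub <- apply_vsa(ind, rec, battery)
  changed <- sub$function_id[sub$value != ind$value | sub$source != ind$source]
  expect_setequal(changed, c("i_p_compaction", "i_p_aggstab"))
  expect_equal(sub$value[sub$function_id == "i_p_compaction"], 0)
  expect_equal(sub$value[sub$function_id == "i_p_aggstab"], 0.5)
  expect_equal(sub$source[sub$function_id == "i_p_compaction"], "vsa")
  # idempotent
  expect_equal(apply_vsa(sub, rec, battery), sub)
})

test_that("compaction rated poor forces the indicator to 0 regardless of the model value", {
  battery <- default_battery()
  for (bd in c(1.0, 1.45, 1.9)) {
    rec <- add_vsa(make_field(bulk_density = bd), "good",
                   compaction = "poor")
    sub <- apply_vsa(evaluate_battery(battery, rec), rec, battery)
    expect_equal(sub$value[sub$function_id == "i_p_compaction"], 0)
  }
})

make_vec <- function(values) {
  battery <- default_battery()
  tibble::tibble(
    function_id = vapply(battery$functions, `[[`, character(1), "id"),
    category = vapply(battery$functions, `[[`, character(1), "category"),
    value = values
  )
}

test_that("with no deficiency all benefits are zero and ties break lexicographically", {
  vec <- make_vec(rep(1, 22))
  rec <- recommend_category(vec, "physical", default_practices(),
                            land_use = "arable", soil_type = "sand")
  expect_true(all(rec$benefit == 0))
  expect_true(all(rec$no_deficiency))
  applicable <- rec$practice_id
  expect_equal(rec$practice_id[rec$best], sort(applicable)[1])
})

test_that("a lone compaction deficiency is assigned to the subsoil-compaction practice", {
  values <- rep(1, 22)
  vec <- make_vec(values)
  vec$value[vec$function_id == "i_p_compaction"] <- 0.2
  rec <- recommend_category(vec, "physical", default_practices(),
                            land_use = "arable", soil_type = "sand")
  # brute force over all practices: only M11 (and weakly M4) touch compaction
  expect_equal(rec$practice_id[rec$best], "M11")
  expect_equal(rec$benefit[rec$best], 1.0 * (1 - 0.2))
})

test_that("benefit never increases when an indicator improves", {
  set.seed(31)
  practices <- default_practices()
  for (i in 1:25) {
    vec <- make_vec(stats::runif(22))
    base <- recommend_category(vec, "chemical", practices,
                               land_use = "maize", soil_type = "clay")
    j <- sample(which(vec$category == "chemical"), 1)
    vec2 <- vec
    vec2$value[j] <- min(1, vec2$value[j] + stats::runif(1))
    after <- recommend_category(vec2, "chemical", practices,
                                land_use = "maize", soil_type = "clay")
    m <- match(base$practice_id, after$practice_id)
    expect_true(all(after$benefit[m] <= base$benefit + 1e-12))
  }
})

test_that("zero-effectiveness practices never outrank effective ones; output is deterministic", {
  vec <- make_vec(rep(0.3, 22))
  practices <- default_practices()
  rec1 <- recommend_category(vec, "biological", practices,
                             land_use = "grassland", soil_type = "peat")
  rec2 <- recommend_category(vec, "biological", practices,
                             land_use = "grassland", soil_type = "peat")
  expect_identical(rec1, rec2)
  positive <- rec1$benefit > 0
  expect_true(all(rec1$rank[positive] < min(rec1$rank[!positive])))
})

test_that("recommend_field advises per category on the most recent year", {
  rec <- make_field(years = 3, bulk_density = 1.9)
  out <- recommend_field(rec)
  expect_setequal(unique(out$category),
                  c("chemical", "physical", "biological", "environmental"))
  best_phys <- out[out$category == "physical" & out$best, ]
  expect_equal(best_phys$practice_id, "M11")
})
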
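# Category matching, criterion evaluation, points scoring and the
# end-to-end classify path, cross-checked against a naive evaluator that
# re-reads the YAML configs.

registry <- load_model_registry()

test_that("category assignment is priority-ordered first match with catch-all", {
  toy <- model_definition("toy", "threshold", category_rules = list(
    category_rule("drinks", priority = 1, is_drink = TRUE),
    category_rule("cereal", priority = 2, tags_any = "breakfast_cereal"),
    category_rule("other", priority = 3, catch_all = TRUE)))
  expect_identical(assign_category(fr("a", drink = TRUE,
                                      category = "fatty_sugary",
                                      subtag = "drink"), toy), "drinks")
  expect_identical(assign_category(fr("b", tags = "breakfast_cereal"), toy),
                   "cereal")
  # drink rule outranks the tag rule for a tagged drink
  expect_identical(assign_category(
    fr("c", drink = TRUE, tags = "breakfast_cereal",
       category = "fatty_sugary", subtag = "drink"), toy), "drinks")
  expect_identical(assign_category(fr("d"), toy), "other")

  one_cat <- model_definition("one", "threshold", category_rules = list(
    category_rule("all", catch_all = TRUE)))
  expect_identical(assign_category(fr("x"), one_cat), "all")
})

test_that("UK model splits foods and drinks; EU Pledge matches printed categories", {
  expect_identical(assign_category(fr("f"), registry$uk), "food")
  expect_identical(assign_category(
    fr("d", drink = TRUE, category = "fatty_sugary", subtag = "drink"),
    registry$uk), "drink")
  expect_identical(
    assign_category(fr("cer", tags = "breakfast_cereal"),
                    registry$eu_pledge), "breakfast_cereals")
  expect_identical(
    assign_category(fr("m", tags = "milk"), registry$eu_pledge),
    "milk_and_milk_substitutes")
})

test_that("criterion evaluation converts bases and respects boundaries exactly", {
  le300 <- criterion("sodium_mg", "<=", 300)
  at <- evaluate_criterion(fr("a", sodium_mg = 300), le300)
  expect_true(at$pass)
  expect_equal(at$observed, 300)
  expect_false(evaluate_criterion(fr("b", sodium_mg = 300.1), le300)$pass)

  per_serv <- criterion("total_fat_g", "<=", 3, basis = "per_serving")
  o <- evaluate_criterion(fr("c", total_fat_g = 5, serving = 50), per_serv)
  expect_equal(o$observed, 2.5)
  expect_true(o$pass)

  pct <- criterion("saturated_fat_g", "<=", 10, basis = "pct_energy")
  # 2 g sat fat x 9 kcal/g out of 418.4 kJ (=100 kcal) -> 18% of energy
  o2 <- evaluate_criterion(fr("d", energy_kJ = 418.4, saturated_fat_g = 2), pct)
  expect_equal(o2$observed, 18)
  expect_false(o2$pass)

  per_kcal <- criterion("sodium_mg", "<=", 120, basis = "per_100kcal")
  o3 <- evaluate_criterion(fr("e", energy_kJ = 836.8, sodium_mg = 200),
                           per_kcal)
  expect_equal(o3$observed, 100)  # 200 mg over 200 kcal
  expect_true(o3$pass)
})

test_that("missing inputs are hard errors naming food and nutrient", {
  f <- food_record("nofibre", nutrients = nutrient_composition(sodium_mg = 10))
  expect_error(evaluate_criterion(f, criterion("fibre_g", ">=", 1), "m"),
               regexp = "nofibre.*fibre_g", class = "npm_missing_nutrient")
  noserv <- food_record("ns", nutrients = nc_full())
  expect_error(
    evaluate_criterion(noserv, criterion("sodium_mg", "<=", 100,
                                         basis = "per_serving")),
    class = "npm_missing_serving")
  expect_error(
    evaluate_criterion(fr("t"), criterion("sodium_mg", "<=", NA), "danish"),
    class = "npm_todo_threshold")
})

test_that("points scoring matches hand-worked examples", {
  uk <- registry$uk$points

  water <- nutrient_composition(
    energy_kJ = 0, total_fat_g = 0, saturated_fat_g = 0, trans_fat_g = 0,
    cholesterol_mg = 0, total_sugar_g = 0, added_sugar_g = 0, sodium_mg = 0,
    protein_g = 0, fibre_g = 0, fruit_veg_nut_pct = 0)
  res <- score_points(water, uk, is_drink = TRUE)
  expect_equal(res$score, 0)
  expect_true(res$approved)  # 0 < drink threshold of 1
  expect_false(score_points(water, uk, is_drink = TRUE,
                            )$score >= 1)

  # worked food: energy 1500 kJ -> 4 pts; sat fat 3 g sits ON the 3-g
  # bound (strict) -> 2 pts; sugar 20 g -> 4; sodium 500 mg -> 5; A = 15.
  # A >= 11 and no fruit/veg points, so protein (2 g -> 1 pt) is barred;
  # C = 1 (fibre 1 g). Score 14: rejected as a food.
  worked <- nc_full(energy_kJ = 1500, saturated_fat_g = 3,
                    total_sugar_g = 20, sodium_mg = 500,
                    fruit_veg_nut_pct = 0, fibre_g = 1, protein_g = 2)
  res <- score_points(worked, uk, is_drink = FALSE)
  expect_equal(res$a_points, 15)
  expect_equal(res$c_points, 1)
  expect_equal(res$score, 14)
  expect_false(res$approved)
  expect_false(res$protein_credited)

  # protein credit restored by maximum fruit/veg/nuts points
  fvn_high <- nc_full(energy_kJ = 1500, saturated_fat_g = 3,
                      total_sugar_g = 20, sodium_mg = 500,
                      fruit_veg_nut_pct = 85, fibre_g = 1, protein_g = 2)
  res2 <- score_points(fvn_high, uk, is_drink = FALSE)
  expect_true(res2$protein_credited)
  expect_equal(res2$c_points, 5 + 1 + 1)

  # boundary exactness: sat fat exactly 1 g earns no points
  expect_equal(score_points(nc_full(saturated_fat_g = 1, energy_kJ = 0,
                                    total_sugar_g = 0, sodium_mg = 0,
                                    fibre_g = 0, protein_g = 0),
                            uk)$a_points, 0)
})

test_that("fibre assay convention selects the matching points column", {
  base <- list(energy_kJ = 0, saturated_fat_g = 0, total_sugar_g = 0,
               sodium_mg = 0, fruit_veg_nut_pct = 0, protein_g = 0)
  nsp <- do.call(nc_full, c(base, fibre_g = 0.8, fibre_method = "NSP"))
  aoac <- do.call(nc_full, c(base, fibre_g = 0.8, fibre_method = "AOAC"))
  uk <- registry$uk$points
  expect_equal(score_points(nsp, uk)$c_points, 1)   # 0.8 > 0.7 NSP bound
  expect_equal(score_points(aoac, uk)$c_points, 0)  # 0.8 <= 0.9 AOAC bound
})

test_that("archetypes classify as expected under all complete models", {
  water <- archetype_food("water", "w")
  peas <- archetype_food("garden_peas", "p")
  conf <- archetype_food("confectionery", "c")
  for (mid in complete_models(registry)) {
    expect_true(classify(water, registry[[mid]])$approved, label = mid)
    expect_true(classify(peas, registry[[mid]])$approved, label = mid)
    expect_false(classify(conf, registry[[mid]])$approved, label = mid)
  }
})

test_that("audit trail lists every evaluated criterion exactly once", {
  f <- fr("a", drink = TRUE, category = "fatty_sugary", subtag = "drink")
  res <- classify(f, registry$brazilian)
  expect_identical(res$matched_category, "drinks")
  expect_setequal(res$criterion_outcomes$nutrient,
                  c("total_sugar_g", "saturated_fat_g", "trans_fat_g",
                    "sodium_mg"))
  expect_false(anyDuplicated(res$criterion_outcomes$nutrient) > 0)
  expect_identical(res$approved, all(res$criterion_outcomes$pass))
})

test_that("optional criteria only restrict: toggling on never approves more", {
  toy <- model_definition("toy_opt", "threshold", category_rules = list(
    category_rule("all", catch_all = TRUE, criteria = list(
      criterion("total_sugar_g", "<=", 20),
      criterion("sodium_mg", "<=", 500, optional = TRUE,
                option = "sodium_considered")))),
    options = list(sodium_considered = FALSE))
  set.seed(42)
  for (i in 1:200) {
    f <- random_food(paste0("r", i))
    off <- classify(f, toy)$approved
    on <- classify(f, toy, options = list(sodium_considered = TRUE))$approved
    expect_true(off >= on)  # may flip approved -> not approved, never back
  }
})

test_that("incomplete models refuse to classify and are excluded by default", {
  expect_error(classify(fr("a", tags = "milk"), registry$danish),
               class = "npm_todo_threshold")
  ds <- commercial_dataset(list(fr("a")))
  expect_error(classify_dataset(ds, registry, models = c("uk", "danish")),
               regexp = "danish", class = "npm_todo_threshold")
  expect_setequal(classify_dataset(ds, registry)$models,
                  complete_models(registry))
})

test_that("worsening a negative nutrient never rescues a food", {
  set.seed(99)
  negatives <- c("total_sugar_g", "sodium_mg", "saturated_fat_g", "energy_kJ")
  for (i in 1:100) {
    f <- random_food(paste0("m", i))
    for (mid in complete_models(registry)) {
      base <- classify(f, registry[[mid]])
      worse <- f
      nut <- sample(negatives, 1)
      bump <- runif(1, 0, 2) * c(total_sugar_g = 10, sodium_mg = 300,
                                 saturated_fat_g = 4, energy_kJ = 800)[[nut]]
      v <- as.list(worse$nutrients$values)
      v[[nut]] <- v[[nut]] + bump
      if (nut == "energy_kJ") v[["energy_kcal"]] <- NULL
      worse$nutrients <- nutrient_composition(v[!vapply(v, is.na, TRUE)],
                                              fibre_method = f$nutrients$fibre_method)
      after <- classify(worse, registry[[mid]])
      expect_true(base$approved >= after$approved,
                  label = sprintf("%s %s +%g", mid, nut, bump))
      if (registry[[mid]]$mode == "points") {
        expect_gte(after$score, base$score)
      }
    }
  }
})

test_that("classify agrees with the naive YAML-reading evaluator", {
  set.seed(7)
  for (i in 1:250) {
    f <- random_food(paste0("o", i))
    for (mid in complete_models(registry)) {
      expect_identical(classify(f, registry[[mid]])$approved,
                       naive_classify(f, shipped_model_path(mid)),
                       label = sprintf("food %d model %s", i, mid))
    }
  }
})

test_that("malformed model files fail loudly", {
  bad1 <- withr::local_tempfile(fileext = ".yaml")
  writeLines("mode: threshold", bad1)
  expect_error(load_model(bad1), regexp = "model_id",
               class = "npm_bad_model_file")

  bad2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("model_id: x", "mode: threshold", "categories:",
               "  - category_id: a", "    match: {is_drink: true}"), bad2)
  expect_error(load_model(bad2), regexp = "catch-all",
               class = "npm_bad_model")

  bad3 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("model_id: x", "mode: threshold", "categories:",
               "  - category_id: a", "    match: {catch_all: true}",
               "    criteria:",
               "      - {nutrient: sodium_mg, comparator: '!=', threshold: 1}"),
             bad3)
  expect_error(load_model(bad3), class = "npm_bad_model")
})
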
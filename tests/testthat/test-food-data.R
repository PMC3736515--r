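# Domain types and the dataset-assembly operations.

test_that("nutrient composition enforces its invariants", {
  expect_error(nutrient_composition(sodium_mg = -1), class = "npm_bad_nutrient")
  expect_error(nutrient_composition(fruit_veg_nut_pct = 101),
               class = "npm_bad_nutrient")
  expect_error(nutrient_composition(banana = 2), class = "npm_bad_nutrient")
  # kJ and kcal must agree within 2% of 4.184 kJ/kcal
  expect_error(nutrient_composition(energy_kJ = 500, energy_kcal = 100),
               class = "npm_bad_nutrient")
  ok <- nutrient_composition(energy_kJ = 418.4, energy_kcal = 100)
  expect_equal(nutrient_value(ok, "energy_kJ"), 418.4)
  # absent fields are NA, not zero
  expect_true(is.na(nutrient_value(ok, "fibre_g")))
})

test_that("food records validate category, counts and serving size", {
  expect_error(food_record("x", food_guide_category = "sweets"),
               class = "npm_bad_record")
  expect_error(food_record("x", commercial_count = -1), class = "npm_bad_record")
  expect_error(food_record("x", commercial_count = 1.5), class = "npm_bad_record")
  expect_error(food_record("x", serving_size_g = 0), class = "npm_bad_record")
  expect_error(food_record("x", food_guide_category = "fatty_sugary"),
               class = "npm_bad_record")  # subtag mandatory for fatty/sugary
  f <- food_record("x", food_guide_category = "fatty_sugary",
                   fatty_sugary_subtag = "snack")
  expect_s3_class(f, "food_record")
})

test_that("dataset totals always equal the sum of per-food counts", {
  foods <- list(fr("a", count = 3L), fr("b", count = 7L), fr("c", count = 0L))
  ds <- commercial_dataset(foods)
  expect_identical(ds$total_commercials, 10L)
  expect_error(commercial_dataset(list(fr("a"), fr("a"))),
               class = "npm_bad_record")
})

test_that("food tables round-trip through CSV", {
  ds <- commercial_dataset(list(
    fr("a", count = 5L, category = "milk_dairy", tags = c("milk", "yoghurt")),
    fr("b", count = 2L, category = "fatty_sugary", subtag = "drink",
       drink = TRUE)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_food_table(ds, path)
  back <- read_food_table(path)
  expect_equal(as.data.frame(back), as.data.frame(ds))
  expect_identical(back$total_commercials, 7L)
})

test_that("readers reject unknown columns unless permissive", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- as.data.frame(commercial_dataset(list(fr("a"))))
  df$surprise <- 1
  write.csv(df, path, row.names = FALSE)
  expect_error(read_food_table(path), class = "npm_bad_table")
  expect_silent(ds <- read_food_table(path, permissive = TRUE))
  expect_length(ds$foods, 1L)
})

# ---- exclusions -------------------------------------------------------

test_that("all four exclusion classes are removed and others kept", {
  raw <- list(
    fr("keep1"), fr("keep2", count = 9L), fr("keep3", count = 4L),
    food_record("alc", exclusion_tags = "alcohol_tea_coffee_gum"),
    food_record("shop", exclusion_tags = "broad_range_retailer"),
    food_record("baby", exclusion_tags = "baby_toddler_food"),
    food_record("shake", exclusion_tags = "weight_shake"))
  ds <- apply_exclusions(raw)
  expect_setequal(vapply(ds$foods, `[[`, character(1), "id"),
                  c("keep1", "keep2", "keep3"))
  expect_identical(ds$total_commercials, 14L)
})

test_that("exclusions reject unknown tags, pass empty input, ignore order", {
  expect_error(apply_exclusions(list(food_record("x", exclusion_tags = "diet_food"))),
               regexp = "diet_food", class = "npm_bad_exclusion_tag")
  expect_identical(apply_exclusions(list())$total_commercials, 0L)
  raw <- list(fr("a"), food_record("z", exclusion_tags = "weight_shake"),
              fr("b", count = 3L))
  ids1 <- vapply(apply_exclusions(raw)$foods, `[[`, character(1), "id")
  ids2 <- vapply(apply_exclusions(rev(raw))$foods, `[[`, character(1), "id")
  expect_setequal(ids1, ids2)
})

# ---- meal averaging ---------------------------------------------------

test_that("meal averaging is the serving-mass-weighted mean", {
  one <- meal_component(nc_full(sodium_mg = 120), 250)
  expect_equal(nutrient_value(compose_meal(list(one)), "sodium_mg"), 120)

  two <- list(meal_component(nc_full(sodium_mg = 100), 100),
              meal_component(nc_full(sodium_mg = 300), 100))
  expect_equal(nutrient_value(compose_meal(two), "sodium_mg"), 200)

  meal <- list(
    meal_component(nc_full(sodium_mg = 500), 200),
    meal_component(nc_full(sodium_mg = 300), 100),
    meal_component(nc_full(sodium_mg = 10), 300, role = "drink"))
  avg <- compose_meal(meal)
  expect_equal(nutrient_value(avg, "sodium_mg"), 133000 / 600)
  expect_equal(attr(avg, "serving_size_g"), 600)
})

test_that("meal averaging conserves a constant nutrient for any masses", {
  set.seed(11)
  for (rep in 1:20) {
    masses <- runif(sample(2:5, 1), 10, 500)
    comps <- lapply(masses, function(m)
      meal_component(nc_full(total_sugar_g = 7.3), m))
    expect_equal(nutrient_value(compose_meal(comps), "total_sugar_g"), 7.3)
  }
  # permutation invariance
  comps <- lapply(c(50, 150, 300), function(m)
    meal_component(nc_full(sodium_mg = m), m))
  expect_equal(compose_meal(comps)$values,
               compose_meal(rev(comps))$values)
})

test_that("meal averaging errors on partial nutrients without a policy", {
  partial <- list(
    meal_component(nc_full(), 100),
    meal_component(nutrient_composition(sodium_mg = 50), 100))
  expect_error(compose_meal(partial), regexp = "energy_kJ",
               class = "npm_partial_nutrient")
  filled <- compose_meal(partial, fill = "zero")
  expect_equal(nutrient_value(filled, "energy_kJ"), 200)  # (400+0)/2
})

# ---- brand representatives --------------------------------------------

test_that("brand selection is uniform, seeded and reproducible", {
  range12 <- lapply(sprintf("flavour_%02d", 1:12), fr)
  expect_identical(select_brand_representative(range12[1], 7)$id,
                   "flavour_01")
  a <- select_brand_representative(range12, 123)
  b <- select_brand_representative(range12, 123)
  expect_identical(a$id, b$id)
  expect_error(select_brand_representative(list(), 1), class = "npm_bad_brand")

  draws <- vapply(1:12000, function(s)
    select_brand_representative(range12, s)$id, character(1))
  freq <- table(draws)
  expect_length(freq, 12L)
  p <- 1 / 12
  sd3 <- 3 * sqrt(12000 * p * (1 - p))
  expect_true(all(abs(freq - 1000) < sd3))
})

# ---- supplementation --------------------------------------------------

test_that("branded values take precedence over generic fills", {
  branded <- nutrient_composition(total_sugar_g = 10)
  generic <- nutrient_composition(total_sugar_g = 12, sodium_mg = 400,
                                  fibre_g = 1)
  out <- supplement_nutrients(branded, generic)
  expect_equal(nutrient_value(out, "total_sugar_g"), 10)
  expect_equal(nutrient_value(out, "sodium_mg"), 400)
  expect_equal(nutrient_value(out, "fibre_g"), 1)
  expect_setequal(attr(out, "filled"), c("sodium_mg", "fibre_g"))

  complete <- nc_full()
  expect_length(attr(supplement_nutrients(complete, generic), "filled"), 0L)
})

test_that("supplementation is idempotent and flags mixed provenance", {
  branded <- nutrient_composition(total_sugar_g = 10)
  generic <- nutrient_composition(total_sugar_g = 12, fibre_g = 2.1)
  once <- supplement_nutrients(branded, generic)
  twice <- supplement_nutrients(once, generic)
  expect_equal(once$values, twice$values)

  f <- food_record("x", nutrients = branded)
  f2 <- supplement_food(f, generic)
  expect_identical(f2$data_source, "mixed")
  expect_equal(nutrient_value(f2$nutrients, "fibre_g"), 2.1)

  expect_error(
    supplement_nutrients(branded, generic, required = c("sodium_mg")),
    regexp = "sodium_mg", class = "npm_missing_nutrient")
})

# ---- validity correlation ---------------------------------------------

test_that("validity correlation reproduces textbook Pearson arithmetic", {
  ident <- validity_correlation(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(ident$r, 1)

  lin <- validity_correlation(branded = c(1, 2, 3), generic = c(2, 4, 6))
  expect_equal(lin$r, 1)
  expect_equal(lin$slope, 2)

  # hand-computed: r = 5.5 / sqrt(5 * 8.75)
  hand <- validity_correlation(branded = c(1, 2, 3, 4),
                               generic = c(1, 3, 2, 5))
  expect_equal(hand$r, 5.5 / sqrt(5 * 8.75), tolerance = 1e-12)

  flat <- validity_correlation(c(1, 1, 1), c(1, 2, 3))
  expect_true(flat$degenerate)
  expect_true(is.na(flat$r))
  expect_error(validity_correlation(c(1, 2), c(1, 2)),
               class = "npm_bad_validity")
})
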
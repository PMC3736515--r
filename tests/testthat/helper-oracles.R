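# Independent brute-force oracles used to cross-check the engine and the
# agreement statistics. These deliberately re-read model configuration
# files and re-implement the arithmetic naively; they never call the
# package's evaluation path.

# --- naive model evaluator ---------------------------------------------

naive_points_for <- function(pairs, value) {
  pts <- 0
  for (pr in pairs) if (value > pr[[1]]) pts <- pr[[2]]
  pts
}

naive_observed <- function(food, crit) {
  nut <- crit$nutrient
  raw <- if (nut == "micronutrient_count") {
    length(food$nutrients$micronutrient_flags)
  } else {
    food$nutrients$values[[nut]]
  }
  basis <- if (is.null(crit$basis)) "per_100g" else crit$basis
  kcal <- food$nutrients$values[["energy_kcal"]]
  if (is.na(kcal)) kcal <- food$nutrients$values[["energy_kJ"]] / 4.184
  switch(basis,
         per_100g = raw, per_100ml = raw,
         per_serving = raw * food$serving_size_g / 100,
         per_100kcal = raw / kcal * 100,
         pct_energy = {
           fac <- c(total_fat_g = 9, saturated_fat_g = 9, trans_fat_g = 9,
                    total_sugar_g = 4, added_sugar_g = 4, protein_g = 4,
                    fibre_g = 2)[[nut]]
           raw * fac / kcal * 100
         })
}

naive_rule_matches <- function(cy, food) {
  m <- cy$match
  if (isTRUE(m$catch_all)) return(TRUE)
  ok <- FALSE
  if (!is.null(m$is_drink)) {
    if (!identical(food$is_drink, m$is_drink)) return(FALSE)
    ok <- TRUE
  }
  if (!is.null(m$tags_any)) {
    if (!any(unlist(m$tags_any) %in% food$model_category_tags)) return(FALSE)
    ok <- TRUE
  }
  ok
}

# classify one food straight from the YAML file, checking every criterion
# naively; returns the approved flag
naive_classify <- function(food, yaml_path, options = list()) {
  y <- yaml::read_yaml(yaml_path)
  if (identical(y$mode, "points")) {
    pt <- y$points_table
    val <- function(f) {
      v <- food$nutrients$values[[f]]
      if (f == "energy_kJ" && is.na(v)) {
        v <- food$nutrients$values[["energy_kcal"]] * 4.184
      }
      v
    }
    a <- 0
    for (nm in names(pt$a_components)) {
      a <- a + min(naive_points_for(pt$a_components[[nm]], val(nm)), 10)
    }
    fvn <- naive_points_for(pt$c_components$fruit_veg_nut_pct,
                            val("fruit_veg_nut_pct"))
    fib_tab <- if (identical(food$nutrients$fibre_method, "AOAC")) {
      pt$c_components$fibre_g_aoac
    } else pt$c_components$fibre_g_nsp
    fib <- naive_points_for(fib_tab, val("fibre_g"))
    pro <- naive_points_for(pt$c_components$protein_g, val("protein_g"))
    if (a >= pt$protein_cap_a_points && fvn < pt$protein_exempt_fvn_points) {
      pro <- 0
    }
    score <- a - (fvn + fib + pro)
    lim <- if (food$is_drink) pt$fail_threshold_drink else pt$fail_threshold_food
    return(score < lim)
  }
  cats <- y$categories[order(vapply(y$categories, function(cc)
    as.integer(cc$priority), integer(1)))]
  matched <- NULL
  for (cy in cats) {
    if (naive_rule_matches(cy, food)) { matched <- cy; break }
  }
  stopifnot(!is.null(matched))
  for (crit in matched$criteria) {
    if (isTRUE(crit$optional) && !isTRUE(options[[crit$option]])) next
    stopifnot(!identical(crit$threshold, "TODO"))
    obs <- naive_observed(food, crit)
    pass <- switch(crit$comparator,
                   "<=" = obs <= crit$threshold, "<" = obs < crit$threshold,
                   ">=" = obs >= crit$threshold, ">" = obs > crit$threshold)
    if (!pass) return(FALSE)
  }
  TRUE
}

# --- brute-force weighted kappa ----------------------------------------

# expand each food into `weight` identical unit rows, then do the
# textbook unweighted contingency arithmetic
brute_kappa <- function(a, b, w) {
  stopifnot(all(w == round(w)), all(w >= 0))
  aa <- rep(a, times = w); bb <- rep(b, times = w)
  n <- length(aa)
  po <- mean(aa == bb)
  if (po == 1) return(1)
  pe <- mean(aa) * mean(bb) + mean(!aa) * mean(!bb)
  (po - pe) / (1 - pe)
}

# --- fixture builders --------------------------------------------------

nc_full <- function(energy_kJ = 400, saturated_fat_g = 1, total_sugar_g = 5,
                    sodium_mg = 100, fruit_veg_nut_pct = 0, fibre_g = 1,
                    protein_g = 3, total_fat_g = 2, trans_fat_g = 0,
                    cholesterol_mg = 0, added_sugar_g = 2,
                    fibre_method = "NSP") {
  nutrient_composition(
    energy_kJ = energy_kJ, total_fat_g = total_fat_g,
    saturated_fat_g = saturated_fat_g, trans_fat_g = trans_fat_g,
    cholesterol_mg = cholesterol_mg, total_sugar_g = total_sugar_g,
    added_sugar_g = added_sugar_g, sodium_mg = sodium_mg,
    protein_g = protein_g, fibre_g = fibre_g,
    fruit_veg_nut_pct = fruit_veg_nut_pct, fibre_method = fibre_method)
}

fr <- function(id, ..., count = 1L, category = "miscellaneous",
               subtag = NA_character_, drink = FALSE, serving = 100,
               tags = character()) {
  food_record(id = id, nutrients = nc_full(...), commercial_count = count,
              food_guide_category = category, fatty_sugary_subtag = subtag,
              serving_size_g = serving, is_drink = drink,
              model_category_tags = tags)
}

# random fully specified food spanning the shipped models' boundaries
random_food <- function(id, drink = NA) {
  if (is.na(drink)) drink <- runif(1) < 0.2
  fr(id,
     energy_kJ = runif(1, 0, 3700),
     saturated_fat_g = runif(1, 0, 12),
     total_sugar_g = runif(1, 0, 50),
     sodium_mg = runif(1, 0, 1200),
     fruit_veg_nut_pct = sample(c(0, runif(1, 0, 100)), 1),
     fibre_g = runif(1, 0, 6),
     protein_g = runif(1, 0, 12),
     total_fat_g = runif(1, 0, 20),
     trans_fat_g = runif(1, 0, 1),
     fibre_method = sample(c("NSP", "AOAC"), 1),
     drink = drink,
     category = if (drink) "fatty_sugary" else "miscellaneous",
     subtag = if (drink) "drink" else NA_character_,
     serving = runif(1, 20, 400))
}

shipped_model_path <- function(model_id) {
  system.file("models", paste0(model_id, ".yaml"), package = "npmagree")
}
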
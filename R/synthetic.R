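# Synthetic advertised-food datasets. The generator emulates the
# statistical structure of the published 2008 UK dataset -- the food-guide
# category mix (336 foods, 11 763 commercials), heavy-tailed broadcast
# counts, and per-category nutrient marginals spanning the pass/fail
# boundaries of the shipped models -- so every pipeline stage can be
# exercised and tested without the unavailable real data. It does not
# attempt to mimic real brands or the true joint nutrient distribution.

# Table-1 category mix: foods per category (fatty/sugary split into its
# three sub-groups)
DEFAULT_CATEGORY_COUNTS <- c(
  bread_cereals_potatoes = 51, composite = 80,
  fatty_sugary_snack = 91, fatty_sugary_not_snack = 14,
  fatty_sugary_drink = 20, fruit_veg = 10, meat_fish_alternatives = 15,
  milk_dairy = 41, miscellaneous = 14
)

#' Configuration for the synthetic dataset generator
#'
#' Defaults reproduce the published dataset's shape: 336 foods across the
#' food-guide categories in their published proportions and 11 763
#' commercials in total, with rounded log-normal broadcast counts.
#'
#' @param n_foods number of foods to generate (archetypes included).
#' @param category_counts named vector over the nine generator categories
#'   (the seven food-guide groups with fatty/sugary split three ways);
#'   used as multinomial proportions.
#' @param total_commercials target total broadcast count; counts are
#'   drawn log-normally, floored at 1 and rescaled to hit this exactly.
#' @param count_meanlog,count_sdlog log-normal parameters of the raw
#'   per-food broadcast count before rescaling.
#' @param nutrient_params data.frame of truncated log-normal parameters
#'   (`category`, `nutrient`, `meanlog`, `sdlog`, `max`); defaults to the
#'   shipped fixture `nutrient_distributions.csv`.
#' @param archetypes archetype foods injected verbatim: any of
#'   `"water"`, `"garden_peas"`, `"confectionery"`.
#' @param seed mandatory integer seed; echoed into provenance.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_foods = 336,
                             category_counts = DEFAULT_CATEGORY_COUNTS,
                             total_commercials = 11763,
                             count_meanlog = 2.5, count_sdlog = 1.3,
                             nutrient_params = NULL,
                             archetypes = c("water", "garden_peas",
                                            "confectionery"),
                             seed) {
  if (missing(seed) || !is_scalar_number(seed)) {
    abort_npm("generator_config requires an explicit integer seed",
              "npm_bad_config")
  }
  if (!is_scalar_number(n_foods) || n_foods < 1) {
    abort_npm("n_foods must be at least 1", "npm_bad_config")
  }
  category_counts <- category_counts[category_counts > 0]
  if (!length(category_counts)) {
    abort_npm("category_counts must have at least one positive entry",
              "npm_bad_config")
  }
  bad <- setdiff(names(category_counts), names(DEFAULT_CATEGORY_COUNTS))
  if (length(bad)) {
    abort_npm(sprintf("unknown generator categories: %s",
                      paste(bad, collapse = ", ")), "npm_bad_config")
  }
  if (is.null(nutrient_params)) {
    nutrient_params <- utils::read.csv(
      system.file("extdata", "nutrient_distributions.csv",
                  package = "npmagree"), stringsAsFactors = FALSE)
  }
  if (length(archetypes)) {
    archetypes <- match.arg(archetypes, several.ok = TRUE)
  } else {
    archetypes <- character()
  }
  if (length(archetypes) > n_foods) archetypes <- archetypes[seq_len(n_foods)]
  structure(list(n_foods = as.integer(n_foods),
                 category_counts = category_counts,
                 total_commercials = as.integer(total_commercials),
                 count_meanlog = count_meanlog, count_sdlog = count_sdlog,
                 nutrient_params = nutrient_params,
                 archetypes = archetypes, seed = as.integer(seed)),
            class = "generator_config")
}

# inverse-CDF draw from a log-normal truncated above at `max`
rtrunc_lnorm <- function(n, meanlog, sdlog, max) {
  u <- stats::runif(n) * stats::plnorm(max, meanlog, sdlog)
  stats::qlnorm(u, meanlog, sdlog)
}

gen_category_table <- function(params, category) {
  p <- params[params$category == category, ]
  if (!nrow(p)) {
    abort_npm(sprintf("no nutrient distribution parameters for category '%s'",
                      category), "npm_bad_config")
  }
  p
}

draw_nutrients <- function(params, category) {
  p <- gen_category_table(params, category)
  v <- stats::setNames(
    vapply(seq_len(nrow(p)), function(i)
      rtrunc_lnorm(1, p$meanlog[i], p$sdlog[i], p$max[i]), numeric(1)),
    p$nutrient)
  # physical consistency: components cannot exceed their parent quantity
  v[["saturated_fat_g"]] <- min(v[["saturated_fat_g"]], v[["total_fat_g"]])
  v[["trans_fat_g"]] <- min(v[["trans_fat_g"]], v[["total_fat_g"]])
  v[["added_sugar_g"]] <- min(v[["added_sugar_g"]], v[["total_sugar_g"]])
  v[["fruit_veg_nut_pct"]] <- min(v[["fruit_veg_nut_pct"]], 100)
  v
}

round_nutrients <- function(v) {
  g <- c("total_fat_g", "saturated_fat_g", "trans_fat_g", "total_sugar_g",
         "added_sugar_g", "protein_g", "fibre_g")
  v[g] <- round(v[g], 2)
  v[c("energy_kJ", "sodium_mg", "cholesterol_mg")] <-
    round(v[c("energy_kJ", "sodium_mg", "cholesterol_mg")])
  v["fruit_veg_nut_pct"] <- round(v["fruit_veg_nut_pct"], 1)
  v
}

nutrients_from_draw <- function(v) {
  v <- round_nutrients(v)
  nutrient_composition(
    energy_kJ = v[["energy_kJ"]],
    energy_kcal = round(v[["energy_kJ"]] / KJ_PER_KCAL, 1),
    total_fat_g = v[["total_fat_g"]],
    saturated_fat_g = v[["saturated_fat_g"]],
    trans_fat_g = v[["trans_fat_g"]],
    cholesterol_mg = v[["cholesterol_mg"]],
    total_sugar_g = v[["total_sugar_g"]],
    added_sugar_g = v[["added_sugar_g"]],
    sodium_mg = v[["sodium_mg"]],
    protein_g = v[["protein_g"]],
    fibre_g = v[["fibre_g"]],
    fruit_veg_nut_pct = v[["fruit_veg_nut_pct"]]
  )
}

food_guide_of <- function(gen_category) {
  if (startsWith(gen_category, "fatty_sugary")) "fatty_sugary"
  else gen_category
}

subtag_of <- function(gen_category) {
  switch(gen_category,
         fatty_sugary_snack = "snack",
         fatty_sugary_not_snack = "not_snack",
         fatty_sugary_drink = "drink",
         NA_character_)
}

archetype_food <- function(which, id) {
  switch(
    which,
    water = food_record(
      id = id, name = "bottled water (archetype)",
      nutrients = nutrient_composition(
        energy_kJ = 0, energy_kcal = 0, total_fat_g = 0,
        saturated_fat_g = 0, trans_fat_g = 0, cholesterol_mg = 0,
        total_sugar_g = 0, added_sugar_g = 0, sodium_mg = 0,
        protein_g = 0, fibre_g = 0, fruit_veg_nut_pct = 0),
      food_guide_category = "fatty_sugary", fatty_sugary_subtag = "drink",
      serving_size_g = 500, is_drink = TRUE,
      model_category_tags = c("fatty_sugary", "water", "drink"),
      data_source = "generic_table"),
    garden_peas = food_record(
      id = id, name = "garden peas (archetype)",
      nutrients = nutrient_composition(
        energy_kJ = 290, energy_kcal = 69.3, total_fat_g = 0.9,
        saturated_fat_g = 0.2, trans_fat_g = 0, cholesterol_mg = 0,
        total_sugar_g = 2.3, added_sugar_g = 0, sodium_mg = 1,
        protein_g = 5.4, fibre_g = 4.5, fruit_veg_nut_pct = 100),
      food_guide_category = "fruit_veg", serving_size_g = 80,
      model_category_tags = c("fruit_veg", "vegetable"),
      data_source = "generic_table"),
    confectionery = food_record(
      id = id, name = "chocolate confectionery (archetype)",
      nutrients = nutrient_composition(
        energy_kJ = 2200, energy_kcal = 525.8, total_fat_g = 30,
        saturated_fat_g = 18, trans_fat_g = 0.2, cholesterol_mg = 10,
        total_sugar_g = 60, added_sugar_g = 55, sodium_mg = 150,
        protein_g = 5, fibre_g = 1, fruit_veg_nut_pct = 0),
      food_guide_category = "fatty_sugary", fatty_sugary_subtag = "snack",
      serving_size_g = 45,
      model_category_tags = c("fatty_sugary", "confectionery", "snack"),
      data_source = "generic_table")
  )
}

# draw, floor at 1, and rescale broadcast counts to the exact target total
rescale_counts <- function(raw, target) {
  counts <- pmax(1L, as.integer(round(raw * target / sum(raw))))
  diff <- as.integer(target - sum(counts))
  # distribute the integer remainder over the largest counts, keeping >= 1
  while (diff != 0) {
    ord <- order(counts, decreasing = TRUE)
    step <- as.integer(sign(diff))
    for (i in ord) {
      if (diff == 0) break
      if (step < 0 && counts[i] <= 1L) next
      counts[i] <- counts[i] + step
      diff <- diff - step
    }
  }
  counts
}

#' Generate a synthetic advertised-food dataset
#'
#' @param config a [generator_config()].
#' @return a [commercial_dataset()] with `config$n_foods` records, exact
#'   total commercials, every food complete for all shipped models'
#'   nutrient sets, and the configured archetypes injected verbatim.
#'   Identical seeds give identical datasets.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr_seed(config$seed, {
    arch_cat <- c(water = "fatty_sugary_drink", garden_peas = "fruit_veg",
                  confectionery = "fatty_sugary_snack")
    n_arch <- length(config$archetypes)
    n_draw <- config$n_foods - n_arch
    probs <- config$category_counts / sum(config$category_counts)
    cats <- if (n_draw > 0) {
      sample(names(probs), n_draw, replace = TRUE, prob = probs)
    } else character()

    foods <- vector("list", config$n_foods)
    serving_params <- config$nutrient_params[
      config$nutrient_params$nutrient == "serving_size_g", ]
    nut_params <- config$nutrient_params[
      config$nutrient_params$nutrient != "serving_size_g", ]
    for (i in seq_along(cats)) {
      gc <- cats[[i]]
      v <- draw_nutrients(nut_params, gc)
      sp <- serving_params[serving_params$category == gc, ]
      serving <- round(rtrunc_lnorm(1, sp$meanlog, sp$sdlog, sp$max))
      tags <- food_guide_of(gc)
      if (gc == "milk_dairy") tags <- c(tags, "milk")
      if (gc == "bread_cereals_potatoes" && stats::runif(1) < 0.5) {
        tags <- c(tags, "breakfast_cereal")
      }
      foods[[i]] <- food_record(
        id = sprintf("syn_%03d", i), name = sprintf("synthetic %s %d", gc, i),
        nutrients = nutrients_from_draw(v),
        food_guide_category = food_guide_of(gc),
        fatty_sugary_subtag = subtag_of(gc),
        serving_size_g = max(serving, 1),
        is_drink = identical(gc, "fatty_sugary_drink"),
        model_category_tags = tags, data_source = "mixed")
    }
    for (j in seq_along(config$archetypes)) {
      a <- config$archetypes[[j]]
      foods[[n_draw + j]] <- archetype_food(a, sprintf("arch_%s", a))
    }
    raw <- stats::rlnorm(config$n_foods, config$count_meanlog,
                         config$count_sdlog)
    counts <- rescale_counts(raw, config$total_commercials)
    for (i in seq_along(foods)) foods[[i]]$commercial_count <- counts[[i]]
    commercial_dataset(
      foods, provenance = sprintf("synthetic (seed %d)", config$seed))
  })
}

# proposal pools for planted-classification rejection sampling. Pools 1
# and 2 lean strongly approved / strongly rejected; pools 3-5 are
# contrast archetypes (salty-but-otherwise-healthy, energy-dense-plain,
# the food's own category) that realise discordant target combinations.
planted_proposal <- function(nut_params, pool, category) {
  if (pool == 1L) return(draw_nutrients(nut_params, "fruit_veg"))
  if (pool == 2L) return(draw_nutrients(nut_params, "fatty_sugary_snack"))
  if (pool == 3L) {
    v <- draw_nutrients(nut_params, "fruit_veg")
    v[["sodium_mg"]] <- rtrunc_lnorm(1, log(600), 0.3, 1200)
    return(v)
  }
  if (pool == 4L) {
    v <- c(energy_kJ = rtrunc_lnorm(1, log(3000), 0.12, 3700),
           total_fat_g = rtrunc_lnorm(1, log(2), 0.5, 8),
           saturated_fat_g = rtrunc_lnorm(1, log(1), 0.5, 4.5),
           trans_fat_g = rtrunc_lnorm(1, log(0.02), 0.5, 0.3),
           cholesterol_mg = rtrunc_lnorm(1, log(5), 0.8, 50),
           total_sugar_g = rtrunc_lnorm(1, log(5), 0.5, 14),
           added_sugar_g = 0,
           sodium_mg = rtrunc_lnorm(1, log(120), 0.6, 390),
           protein_g = rtrunc_lnorm(1, log(1), 0.4, 1.6),
           fibre_g = rtrunc_lnorm(1, log(0.3), 0.5, 0.7),
           fruit_veg_nut_pct = 0)
    v[["saturated_fat_g"]] <- min(v[["saturated_fat_g"]], v[["total_fat_g"]])
    v[["trans_fat_g"]] <- min(v[["trans_fat_g"]], v[["total_fat_g"]])
    return(v)
  }
  draw_nutrients(nut_params, category)
}

#' Generate a dataset with planted per-model classifications
#'
#' For each food a target approved/rejected flag is drawn per model from
#' the planted rate; nutrient vectors are then rejection-sampled from
#' healthy- or unhealthy-leaning pools until the engine's classification
#' matches every target. The recorded truth is always the engine's own
#' classification, so empirical approval rates are binomially distributed
#' around the planted rates.
#'
#' @param config a [generator_config()].
#' @param planted_rates named numeric vector of target approval
#'   probabilities, names = model ids; every named model must be complete
#'   in `registry`.
#' @param registry an `npm_registry` (defaults to the shipped models).
#' @param max_tries rejection-sampling budget per food; exhausting it
#'   (jointly unsatisfiable targets for a degenerate configuration) is an
#'   error.
#' @return list with `dataset` (a [commercial_dataset()]) and `truth`
#'   (foods x models logical matrix of engine classifications).
#' @export
generate_with_ground_truth <- function(config, planted_rates,
                                       registry = load_model_registry(),
                                       max_tries = 500L) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(names(planted_rates)) || !length(planted_rates) ||
      any(planted_rates < 0 | planted_rates > 1)) {
    abort_npm("planted_rates must be a named vector of probabilities",
              "npm_bad_config")
  }
  models <- names(planted_rates)
  bad <- setdiff(models, complete_models(registry))
  if (length(bad)) {
    abort_npm(sprintf("planted model(s) not fully specified: %s",
                      paste(bad, collapse = ", ")), "npm_bad_config")
  }
  nut_params <- config$nutrient_params[
    config$nutrient_params$nutrient != "serving_size_g", ]
  serving_params <- config$nutrient_params[
    config$nutrient_params$nutrient == "serving_size_g", ]
  withr_seed(config$seed, {
    probs <- config$category_counts / sum(config$category_counts)
    cats <- sample(names(probs), config$n_foods, replace = TRUE,
                   prob = probs)
    truth <- matrix(NA, config$n_foods, length(models),
                    dimnames = list(NULL, models))
    foods <- vector("list", config$n_foods)
    for (i in seq_len(config$n_foods)) {
      target <- stats::rbinom(length(models), 1, planted_rates) == 1
      gc <- cats[[i]]
      sp <- serving_params[serving_params$category == gc, ]
      serving <- max(round(rtrunc_lnorm(1, sp$meanlog, sp$sdlog, sp$max)), 1)
      found <- FALSE
      for (try in seq_len(max_tries)) {
        pool <- if (all(target)) 1L
          else if (!any(target)) 2L
          else (try - 1L) %% 5L + 1L
        v <- planted_proposal(nut_params, pool, gc)
        cand <- food_record(
          id = sprintf("gt_%03d", i), name = sprintf("planted food %d", i),
          nutrients = nutrients_from_draw(v),
          food_guide_category = food_guide_of(gc),
          fatty_sugary_subtag = subtag_of(gc),
          serving_size_g = serving,
          is_drink = identical(gc, "fatty_sugary_drink"),
          model_category_tags = food_guide_of(gc), data_source = "mixed")
        flags <- vapply(models, function(mid)
          classify(cand, registry[[mid]])$approved, logical(1))
        if (all(flags == target)) {
          foods[[i]] <- cand
          truth[i, ] <- flags
          found <- TRUE
          break
        }
      }
      if (!found) {
        abort_npm(sprintf(
          "food %d: could not realise planted targets (%s) in %d tries -- unsatisfiable rate for this model configuration",
          i, paste(sprintf("%s=%d", models, target), collapse = ","),
          max_tries), "npm_unsatisfiable")
      }
    }
    raw <- stats::rlnorm(config$n_foods, config$count_meanlog,
                         config$count_sdlog)
    counts <- rescale_counts(raw, config$total_commercials)
    for (i in seq_along(foods)) foods[[i]]$commercial_count <- counts[[i]]
    ds <- commercial_dataset(
      foods, provenance = sprintf("synthetic planted (seed %d)", config$seed))
    rownames(truth) <- vapply(foods, `[[`, character(1), "id")
    list(dataset = ds, truth = truth)
  })
}
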
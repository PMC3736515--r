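# The evaluation engine: category assignment, criterion evaluation with
# basis conversion, points scoring, and the per-food classification with a
# full audit trail. Missing nutrients are a hard error, never a silent
# pass or fail -- foods are expected to be supplemented to completeness
# before classification, as in the source data assembly.

#' Assign a food to a model category
#'
#' Category rules are tried in priority order; the first whose predicate
#' (tag membership and/or drink flag) matches wins. Every shipped model
#' ends with a catch-all, so assignment is total.
#'
#' @param food a [food_record()].
#' @param model an `npm_model` in threshold mode (points-mode models split
#'   only into `"food"` and `"drink"`).
#' @return the matched `category_id` (character).
#' @export
assign_category <- function(food, model) {
  stopifnot(inherits(food, "food_record"), inherits(model, "npm_model"))
  if (model$mode == "points") {
    return(if (food$is_drink) "drink" else "food")
  }
  for (rule in model$category_rules) {
    if (rule_matches(rule, food)) return(rule$category_id)
  }
  abort_npm(sprintf("model '%s' has no category matching food '%s' (malformed model: no catch-all reached)",
                    model$model_id, food$id), "npm_no_category")
}

#' Evaluate one criterion against a food
#'
#' Converts the food's per-100 g nutrient value to the criterion's basis
#' (`per_serving` multiplies by serving/100; `per_100kcal` and
#' `pct_energy` divide by energy, deriving kcal from kJ at 4.184 kJ/kcal
#' when needed) and applies the comparator exactly: a value equal to an
#' inclusive threshold passes, no rounding is applied before comparison.
#'
#' @param food a [food_record()].
#' @param crit an [criterion()].
#' @param model_id used in error messages.
#' @return list with `observed` (value on the criterion's basis),
#'   `pass` (logical), and the criterion fields.
#' @export
evaluate_criterion <- function(food, crit, model_id = "") {
  stopifnot(inherits(food, "food_record"), inherits(crit, "npm_criterion"))
  if (crit$todo) {
    abort_npm(sprintf("model '%s': criterion on %s has an untranscribed (TODO) threshold",
                      model_id, crit$nutrient), "npm_todo_threshold")
  }
  raw <- if (crit$nutrient == "micronutrient_count") {
    length(food$nutrients$micronutrient_flags)
  } else {
    nutrient_value(food$nutrients, crit$nutrient)
  }
  if (is.na(raw)) {
    abort_npm(sprintf("food '%s', model '%s': nutrient '%s' is absent; supplement before classifying",
                      food$id, model_id, crit$nutrient),
              "npm_missing_nutrient")
  }
  observed <- switch(
    crit$basis,
    per_100g = ,
    per_100ml = raw,
    per_serving = {
      if (is.na(food$serving_size_g)) {
        abort_npm(sprintf("food '%s', model '%s': per-serving criterion on %s needs serving_size_g",
                          food$id, model_id, crit$nutrient),
                  "npm_missing_serving")
      }
      raw * food$serving_size_g / 100
    },
    per_100kcal = {
      kcal <- energy_kcal_of(food$nutrients)
      if (is.na(kcal) || kcal <= 0) {
        abort_npm(sprintf("food '%s', model '%s': per-100kcal criterion on %s needs positive energy",
                          food$id, model_id, crit$nutrient),
                  "npm_missing_nutrient")
      }
      raw / kcal * 100
    },
    pct_energy = {
      kcal <- energy_kcal_of(food$nutrients)
      if (is.na(kcal) || kcal <= 0) {
        abort_npm(sprintf("food '%s', model '%s': %%-energy criterion on %s needs positive energy",
                          food$id, model_id, crit$nutrient),
                  "npm_missing_nutrient")
      }
      fac <- ENERGY_FACTORS_KCAL_PER_G[[crit$nutrient]]
      if (is.null(fac)) {
        abort_npm(sprintf("no energy conversion factor for nutrient '%s'",
                          crit$nutrient), "npm_bad_model")
      }
      raw * fac / kcal * 100
    }
  )
  pass <- switch(crit$comparator,
                 "<=" = observed <= crit$threshold,
                 "<"  = observed <  crit$threshold,
                 ">=" = observed >= crit$threshold,
                 ">"  = observed >  crit$threshold)
  list(nutrient = crit$nutrient, basis = crit$basis,
       comparator = crit$comparator, threshold = crit$threshold,
       observed = observed, pass = pass, optional = crit$optional)
}

#' Score a composition against a points table
#'
#' A-points accrue for energy, saturated fat, total sugar and sodium
#' (up to 10 each); C-points for fruit/veg/nuts, fibre and protein, with
#' protein credited only when A-points stay below the cap or fruit/veg/nuts
#' reaches the exemption level. Score = A - C; foods are approved below
#' the food fail threshold, drinks below the drink one.
#'
#' @param nutrients a [nutrient_composition()] complete for the seven
#'   scored components.
#' @param table an [points_table()].
#' @param is_drink logical: apply the drink pass threshold.
#' @param food_id,model_id labels for the audit trail and errors.
#' @return a `classification_result` with `score`, `a_points`, `c_points`,
#'   per-component breakdown and `approved`.
#' @export
score_points <- function(nutrients, table, is_drink = FALSE,
                         food_id = "", model_id = "uk") {
  stopifnot(inherits(nutrients, "nutrient_composition"),
            inherits(table, "npm_points_table"))
  val <- function(field) {
    v <- if (field == "energy_kJ") energy_kj_of(nutrients)
         else nutrient_value(nutrients, field)
    if (is.na(v)) {
      abort_npm(sprintf("food '%s', model '%s': nutrient '%s' is absent; points scoring needs all seven components",
                        food_id, model_id, field), "npm_missing_nutrient")
    }
    v
  }
  a_pts <- vapply(names(table$a_components), function(nm)
    min(points_for(table$a_components[[nm]], val(nm)), 10), numeric(1))
  a_total <- sum(a_pts)

  fibre_key <- if (identical(nutrients$fibre_method, "AOAC"))
    "fibre_g_aoac" else "fibre_g_nsp"
  fvn_pts <- points_for(table$c_components[["fruit_veg_nut_pct"]],
                        val("fruit_veg_nut_pct"))
  fibre_pts <- points_for(table$c_components[[fibre_key]], val("fibre_g"))
  protein_pts_raw <- points_for(table$c_components[["protein_g"]],
                                val("protein_g"))
  protein_credited <- a_total < table$protein_cap_a_points ||
    fvn_pts >= table$protein_exempt_fvn_points
  protein_pts <- if (protein_credited) protein_pts_raw else 0
  c_total <- fvn_pts + fibre_pts + protein_pts
  score <- a_total - c_total
  threshold <- if (is_drink) table$fail_threshold_drink
               else table$fail_threshold_food
  breakdown <- data.frame(
    component = c(names(table$a_components), "fruit_veg_nut_pct",
                  "fibre_g", "protein_g"),
    side = c(rep("A", length(a_pts)), "C", "C", "C"),
    points = c(unname(a_pts), fvn_pts, fibre_pts, protein_pts),
    stringsAsFactors = FALSE)
  classification_result(
    food_id = food_id, model_id = model_id,
    approved = score < threshold,
    matched_category = if (is_drink) "drink" else "food",
    criterion_outcomes = breakdown,
    score = score, a_points = a_total, c_points = c_total,
    protein_credited = protein_credited)
}

classification_result <- function(food_id, model_id, approved,
                                  matched_category, criterion_outcomes,
                                  score = NA_real_, a_points = NA_real_,
                                  c_points = NA_real_,
                                  protein_credited = NA) {
  structure(list(food_id = food_id, model_id = model_id,
                 approved = approved, matched_category = matched_category,
                 criterion_outcomes = criterion_outcomes, score = score,
                 a_points = a_points, c_points = c_points,
                 protein_credited = protein_credited),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> %s x %s: %s (category %s%s)\n",
              x$food_id, x$model_id,
              if (x$approved) "APPROVED" else "not approved",
              x$matched_category,
              if (!is.na(x$score)) sprintf(", score %g", x$score) else ""))
  invisible(x)
}

#' Classify one food under one model
#'
#' Threshold mode: the food is assigned to its category and every
#' non-optional criterion of that category is evaluated (optional criteria
#' only when their gating option is on); approval requires all evaluated
#' criteria to pass. Points mode: dispatches to [score_points()].
#'
#' @param food a [food_record()].
#' @param model an `npm_model`; must be complete
#'   (see [model_is_complete()]).
#' @param options named list overriding the model's options (e.g.
#'   `list(danish_sodium_considered = TRUE)`).
#' @return a `classification_result` with a per-criterion audit trail.
#' @export
classify <- function(food, model, options = list()) {
  stopifnot(inherits(food, "food_record"), inherits(model, "npm_model"))
  opts <- utils::modifyList(model$options, options)
  if (model$mode == "points") {
    return(score_points(food$nutrients, model$points,
                        is_drink = food$is_drink, food_id = food$id,
                        model_id = model$model_id))
  }
  cat_id <- assign_category(food, model)
  ids <- vapply(model$category_rules, `[[`, character(1), "category_id")
  rule <- model$category_rules[[match(cat_id, ids)]]
  active <- Filter(function(cr) {
    !cr$optional || isTRUE(opts[[cr$option]])
  }, rule$criteria)
  outcomes <- lapply(active, function(cr)
    evaluate_criterion(food, cr, model_id = model$model_id))
  odf <- if (length(outcomes)) {
    do.call(rbind, lapply(outcomes, function(o)
      data.frame(nutrient = o$nutrient, basis = o$basis,
                 comparator = o$comparator, threshold = o$threshold,
                 observed = o$observed, pass = o$pass,
                 optional = o$optional, stringsAsFactors = FALSE)))
  } else {
    data.frame(nutrient = character(), basis = character(),
               comparator = character(), threshold = numeric(),
               observed = numeric(), pass = logical(),
               optional = logical(), stringsAsFactors = FALSE)
  }
  classification_result(
    food_id = food$id, model_id = model$model_id,
    approved = all(odf$pass),  # vacuously TRUE for criterion-free categories
    matched_category = cat_id, criterion_outcomes = odf)
}

#' Classify every food under a set of models
#'
#' @param dataset a [commercial_dataset()].
#' @param registry an `npm_registry`.
#' @param models model ids to apply; defaults to every complete model in
#'   the registry. Requesting an incomplete model is an error naming it.
#' @param options per-run model option overrides.
#' @return a `classification_set`: list with `approved` (foods x models
#'   logical matrix, rownames = food ids), `results` (nested list of
#'   `classification_result`s), `weights`, `dataset`, `models`.
#' @export
classify_dataset <- function(dataset, registry,
                             models = complete_models(registry),
                             options = list()) {
  stopifnot(inherits(dataset, "commercial_dataset"),
            inherits(registry, "npm_registry"))
  missing <- setdiff(models, names(registry))
  if (length(missing)) {
    abort_npm(sprintf("model(s) not in registry: %s",
                      paste(missing, collapse = ", ")), "npm_bad_model")
  }
  incomplete <- models[!vapply(registry[models], model_is_complete,
                               logical(1))]
  if (length(incomplete)) {
    abort_npm(sprintf(
      "model(s) with untranscribed thresholds cannot be run: %s (exclude them or complete the config)",
      paste(incomplete, collapse = ", ")), "npm_todo_threshold")
  }
  ids <- vapply(dataset$foods, `[[`, character(1), "id")
  approved <- matrix(NA, nrow = length(ids), ncol = length(models),
                     dimnames = list(ids, models))
  results <- lapply(models, function(mid) {
    lapply(dataset$foods, classify, model = registry[[mid]],
           options = options)
  })
  names(results) <- models
  for (mid in models) {
    approved[, mid] <- vapply(results[[mid]], `[[`, logical(1), "approved")
  }
  structure(list(approved = approved, results = results,
                 weights = commercial_weights(dataset),
                 dataset = dataset, models = models),
            class = "classification_set")
}

#' @export
print.classification_set <- function(x, ...) {
  cat(sprintf("<classification_set> %d foods x %d models\n",
              nrow(x$approved), ncol(x$approved)))
  print(colSums(x$approved))
  invisible(x)
}
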
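# Declarative nutrient profile model definitions. A model is either
# threshold-mode (priority-ordered category rules, each with a set of
# nutrient criteria that must all pass) or points-mode (an FSA/Ofcom-style
# scoring table). Models are shipped as YAML files under inst/models/ and
# loaded into a registry; a criterion whose threshold is marked TODO makes
# the model "incomplete" and excludes it from default classification runs
# while keeping its structure available for introspection.

MODEL_IDS <- c("brazilian", "danish", "disney", "pepsico", "uk",
               "us_cspi", "us_interagency", "eu_pledge")

CRITERION_BASES <- c("per_100g", "per_100ml", "per_serving", "per_100kcal",
                     "pct_energy")
COMPARATORS <- c("<=", "<", ">=", ">")

CRITERION_NUTRIENTS <- c(NUTRIENT_FIELDS, "micronutrient_count")

#' Construct a single nutrient criterion
#'
#' @param nutrient a name from [NUTRIENT_FIELDS] (or
#'   `"micronutrient_count"` for vitamins/minerals components).
#' @param comparator one of `<=`, `<`, `>=`, `>`; applied exactly, so a
#'   value sitting on an inclusive threshold passes.
#' @param threshold non-negative quantity in the basis units; `NA` marks a
#'   criterion whose published value has not been transcribed (TODO).
#' @param basis `per_100g` (default; per 100 ml for drinks),
#'   `per_serving`, `per_100kcal`, or `pct_energy`.
#' @param optional logical: criterion only evaluated when the option named
#'   in `option` is switched on (e.g. the Danish "further consideration"
#'   sodium criterion).
#' @param option name of the model option gating an optional criterion.
#' @return object of class `npm_criterion`.
#' @export
criterion <- function(nutrient, comparator, threshold, basis = "per_100g",
                      optional = FALSE, option = NA_character_) {
  if (!nutrient %in% CRITERION_NUTRIENTS) {
    abort_npm(sprintf("criterion nutrient '%s' unknown", nutrient),
              "npm_bad_model")
  }
  if (!comparator %in% COMPARATORS) {
    abort_npm(sprintf("criterion comparator '%s' unknown (use one of %s)",
                      comparator, paste(COMPARATORS, collapse = " ")),
              "npm_bad_model")
  }
  if (!basis %in% CRITERION_BASES) {
    abort_npm(sprintf("criterion basis '%s' unknown", basis), "npm_bad_model")
  }
  todo <- length(threshold) == 1L && (is.na(threshold) ||
                                        identical(threshold, "TODO"))
  if (!todo && (!is_scalar_number(threshold) || threshold < 0)) {
    abort_npm("criterion threshold must be a non-negative number or TODO",
              "npm_bad_model")
  }
  structure(list(nutrient = nutrient, comparator = comparator,
                 threshold = if (todo) NA_real_ else as.numeric(threshold),
                 basis = basis, optional = isTRUE(optional),
                 option = option, todo = todo),
            class = "npm_criterion")
}

#' Construct a category rule
#'
#' @param category_id name of the model category.
#' @param criteria list of [criterion()]s that a matched food must all
#'   pass (non-optional ones) to be approved.
#' @param priority integer rank; rules are tried in increasing priority
#'   and the first match wins.
#' @param tags_any match if the food carries any of these category tags.
#' @param is_drink if not `NA`, match only foods with this drink flag.
#' @param catch_all if `TRUE` the rule matches unconditionally; every
#'   model must end with one.
#' @return object of class `npm_category_rule`.
#' @export
category_rule <- function(category_id, criteria = list(), priority = 1L,
                          tags_any = character(), is_drink = NA,
                          catch_all = FALSE) {
  for (cr in criteria) stopifnot(inherits(cr, "npm_criterion"))
  structure(list(category_id = category_id, criteria = criteria,
                 priority = as.integer(priority),
                 tags_any = as.character(tags_any),
                 is_drink = is_drink, catch_all = isTRUE(catch_all)),
            class = "npm_category_rule")
}

rule_matches <- function(rule, food) {
  if (rule$catch_all) return(TRUE)
  if (!is.na(rule$is_drink) && !identical(food$is_drink, rule$is_drink)) {
    return(FALSE)
  }
  if (length(rule$tags_any) &&
      !any(rule$tags_any %in% food$model_category_tags)) {
    return(FALSE)
  }
  # a rule with only an is_drink condition matches on that alone
  !is.na(rule$is_drink) || length(rule$tags_any) > 0L
}

#' Construct a points table (FSA/Ofcom-style scoring)
#'
#' Each component maps to an ordered list of `(strict lower bound, points)`
#' pairs: a value scores the points of the highest bound it exceeds.
#' "A" components are the negative nutrients (energy, saturated fat, total
#' sugar, sodium; up to 10 points each); "C" components are the positive
#' ones (fruit/veg/nuts with attainable points 1, 2 and 5; fibre and
#' protein up to 5). Protein is credited only when A-points are below
#' `protein_cap_a_points` or fruit/veg/nuts scores at least
#' `protein_exempt_fvn_points`. Score = A - C; a food is approved when its
#' score is below `fail_threshold_food` (drinks: `fail_threshold_drink`).
#'
#' @param a_components named list: component -> list of `c(bound, points)`.
#' @param c_components named list, with fibre keyed as `fibre_g_nsp` and
#'   `fibre_g_aoac` for the two assay conventions.
#' @param protein_cap_a_points,protein_exempt_fvn_points,fail_threshold_food,fail_threshold_drink
#'   combination-rule parameters (defaults are the published values).
#' @return object of class `npm_points_table`.
#' @export
points_table <- function(a_components, c_components,
                         protein_cap_a_points = 11,
                         protein_exempt_fvn_points = 5,
                         fail_threshold_food = 4,
                         fail_threshold_drink = 1) {
  chk <- function(pairs, label) {
    b <- vapply(pairs, `[[`, numeric(1), 1L)
    p <- vapply(pairs, `[[`, numeric(1), 2L)
    if (any(diff(b) <= 0) || any(diff(p) <= 0)) {
      abort_npm(sprintf("points table component '%s': bounds and points must be strictly increasing",
                        label), "npm_bad_model")
    }
  }
  for (nm in names(a_components)) {
    chk(a_components[[nm]], nm)
    if (max(vapply(a_components[[nm]], `[[`, numeric(1), 2L)) > 10) {
      abort_npm(sprintf("A component '%s' exceeds 10 points", nm),
                "npm_bad_model")
    }
  }
  for (nm in names(c_components)) {
    chk(c_components[[nm]], nm)
    if (max(vapply(c_components[[nm]], `[[`, numeric(1), 2L)) > 5) {
      abort_npm(sprintf("C component '%s' exceeds 5 points", nm),
                "npm_bad_model")
    }
  }
  structure(list(a_components = a_components, c_components = c_components,
                 protein_cap_a_points = protein_cap_a_points,
                 protein_exempt_fvn_points = protein_exempt_fvn_points,
                 fail_threshold_food = fail_threshold_food,
                 fail_threshold_drink = fail_threshold_drink),
            class = "npm_points_table")
}

points_for <- function(pairs, value) {
  pts <- 0
  for (pr in pairs) if (value > pr[[1L]]) pts <- pr[[2L]] else break
  pts
}

#' Construct a model definition
#'
#' @param model_id identifier, one of the eight compared models or any new
#'   id for user-defined models.
#' @param mode `"threshold"` or `"points"`.
#' @param category_rules list of [category_rule()]s (threshold mode).
#' @param points points table (points mode), a [points_table()].
#' @param name human-readable model name.
#' @param options named list of logical model options (e.g.
#'   `danish_sodium_considered = FALSE`).
#' @param notes free-text provenance / transcription notes.
#' @return object of class `npm_model`. `nutrient_set(model)` introspects
#'   the nutrients it reads; `model_is_complete(model)` is `FALSE` while
#'   any criterion threshold is TODO.
#' @export
model_definition <- function(model_id, mode = c("threshold", "points"),
                             category_rules = list(), points = NULL,
                             name = model_id, options = list(),
                             notes = "") {
  mode <- match.arg(mode)
  if (mode == "threshold") {
    if (!length(category_rules)) {
      abort_npm(sprintf("model '%s': threshold mode needs category rules",
                        model_id), "npm_bad_model")
    }
    if (!any(vapply(category_rules, `[[`, logical(1), "catch_all"))) {
      abort_npm(sprintf("model '%s': a catch-all category rule is mandatory",
                        model_id), "npm_bad_model")
    }
    ord <- order(vapply(category_rules, `[[`, integer(1), "priority"))
    category_rules <- category_rules[ord]
  } else {
    stopifnot(inherits(points, "npm_points_table"))
  }
  structure(list(model_id = model_id, mode = mode,
                 category_rules = category_rules, points = points,
                 name = name, options = options, notes = notes),
            class = "npm_model")
}

#' @export
print.npm_model <- function(x, ...) {
  cat(sprintf("<npm_model> %s (%s mode, %d categories%s)\n",
              x$model_id, x$mode, n_categories(x),
              if (model_is_complete(x)) "" else "; INCOMPLETE"))
  invisible(x)
}

#' Nutrients a model reads
#' @param model an `npm_model`.
#' @param include_optional include nutrients referenced only by optional
#'   ("further consideration") criteria; set `FALSE` to introspect the
#'   nutrient set of the model as applied by default.
#' @return character vector of nutrient field names.
#' @export
nutrient_set <- function(model, include_optional = TRUE) {
  stopifnot(inherits(model, "npm_model"))
  if (model$mode == "points") {
    return(c("energy_kJ", "saturated_fat_g", "total_sugar_g", "sodium_mg",
             "fruit_veg_nut_pct", "fibre_g", "protein_g"))
  }
  nuts <- unlist(lapply(model$category_rules, function(r) {
    crs <- r$criteria
    if (!include_optional) crs <- Filter(function(cr) !cr$optional, crs)
    vapply(crs, `[[`, character(1), "nutrient")
  }))
  sort(unique(nuts))
}

#' Number of categories a model distinguishes
#' @param model an `npm_model`.
#' @return integer; points-mode models count their food/drink split.
#' @export
n_categories <- function(model) {
  stopifnot(inherits(model, "npm_model"))
  if (model$mode == "points") 2L else length(model$category_rules)
}

#' Is every criterion threshold specified?
#' @param model an `npm_model`.
#' @return `TRUE` when the model can be evaluated; `FALSE` while any
#'   criterion threshold is still marked TODO.
#' @export
model_is_complete <- function(model) {
  stopifnot(inherits(model, "npm_model"))
  if (model$mode == "points") return(TRUE)
  !any(unlist(lapply(model$category_rules, function(r)
    vapply(r$criteria, `[[`, logical(1), "todo"))))
}

# ---- YAML loading ------------------------------------------------------

parse_criterion <- function(x, where) {
  for (req in c("nutrient", "comparator", "threshold")) {
    if (is.null(x[[req]])) {
      abort_npm(sprintf("%s: criterion lacks '%s'", where, req),
                "npm_bad_model_file")
    }
  }
  criterion(x$nutrient, x$comparator,
            if (identical(x$threshold, "TODO")) NA else x$threshold,
            basis = x$basis %||% "per_100g",
            optional = isTRUE(x$optional),
            option = x$option %||% NA_character_)
}

parse_pairs <- function(x, where) {
  lapply(x, function(pr) {
    if (length(pr) != 2L) {
      abort_npm(sprintf("%s: points entries must be [bound, points] pairs",
                        where), "npm_bad_model_file")
    }
    c(as.numeric(pr[[1L]]), as.numeric(pr[[2L]]))
  })
}

#' Load one model definition from a YAML file
#'
#' See the files under `system.file("models", package = "npmagree")` for
#' the schema. Violations are fatal with a message naming the file and
#' element.
#'
#' @param path YAML file path.
#' @return an `npm_model`.
#' @export
load_model <- function(path) {
  y <- tryCatch(yaml::read_yaml(path), error = function(e) {
    abort_npm(sprintf("cannot parse model file %s: %s", path,
                      conditionMessage(e)), "npm_bad_model_file")
  })
  for (req in c("model_id", "mode")) {
    if (is.null(y[[req]])) {
      abort_npm(sprintf("%s: missing top-level field '%s'", path, req),
                "npm_bad_model_file")
    }
  }
  if (identical(y$mode, "points")) {
    pt <- y$points_table
    if (is.null(pt)) {
      abort_npm(sprintf("%s: points mode needs a points_table", path),
                "npm_bad_model_file")
    }
    tab <- points_table(
      a_components = stats::setNames(
        lapply(names(pt$a_components), function(nm)
          parse_pairs(pt$a_components[[nm]], paste0(path, ":", nm))),
        names(pt$a_components)),
      c_components = stats::setNames(
        lapply(names(pt$c_components), function(nm)
          parse_pairs(pt$c_components[[nm]], paste0(path, ":", nm))),
        names(pt$c_components)),
      protein_cap_a_points = pt$protein_cap_a_points %||% 11,
      protein_exempt_fvn_points = pt$protein_exempt_fvn_points %||% 5,
      fail_threshold_food = pt$fail_threshold_food %||% 4,
      fail_threshold_drink = pt$fail_threshold_drink %||% 1)
    return(model_definition(y$model_id, "points", points = tab,
                            name = y$name %||% y$model_id,
                            options = y$options %||% list(),
                            notes = y$notes %||% ""))
  }
  if (!identical(y$mode, "threshold")) {
    abort_npm(sprintf("%s: mode must be 'threshold' or 'points', got '%s'",
                      path, y$mode), "npm_bad_model_file")
  }
  if (!length(y$categories)) {
    abort_npm(sprintf("%s: threshold mode needs a categories list", path),
              "npm_bad_model_file")
  }
  rules <- lapply(seq_along(y$categories), function(i) {
    cy <- y$categories[[i]]
    if (is.null(cy$category_id)) {
      abort_npm(sprintf("%s: category %d lacks category_id", path, i),
                "npm_bad_model_file")
    }
    where <- sprintf("%s:%s", path, cy$category_id)
    category_rule(
      category_id = cy$category_id,
      criteria = lapply(cy$criteria %||% list(), parse_criterion,
                        where = where),
      priority = cy$priority %||% i,
      tags_any = unlist(cy$match$tags_any) %||% character(),
      is_drink = cy$match$is_drink %||% NA,
      catch_all = isTRUE(cy$match$catch_all))
  })
  model_definition(y$model_id, "threshold", category_rules = rules,
                   name = y$name %||% y$model_id,
                   options = y$options %||% list(), notes = y$notes %||% "")
}

#' Load a directory of model definitions
#'
#' @param dir directory of `*.yaml` model files; defaults to the eight
#'   shipped model configurations.
#' @return named list of `npm_model`s (class `npm_registry`), keyed by
#'   `model_id`.
#' @export
load_model_registry <- function(dir = system.file("models",
                                                  package = "npmagree")) {
  files <- sort(list.files(dir, pattern = "\\.ya?ml$", full.names = TRUE))
  if (!length(files)) {
    abort_npm(sprintf("no model files found in %s", dir), "npm_bad_model_file")
  }
  models <- lapply(files, load_model)
  ids <- vapply(models, `[[`, character(1), "model_id")
  if (anyDuplicated(ids)) {
    abort_npm(sprintf("duplicate model_id in registry: %s",
                      paste(unique(ids[duplicated(ids)]), collapse = ", ")),
              "npm_bad_model_file")
  }
  structure(stats::setNames(models, ids), class = "npm_registry")
}

#' Summarise a model registry
#'
#' One row per model: mode, category count, completeness, and the nutrient
#' set it reads -- the structural facts reported for the eight compared
#' models.
#'
#' @param registry an `npm_registry` from [load_model_registry()].
#' @return data.frame with columns `model_id`, `mode`, `n_categories`,
#'   `complete`, `n_nutrients`, `nutrients`.
#' @export
registry_summary <- function(registry) {
  stopifnot(inherits(registry, "npm_registry"))
  do.call(rbind, lapply(registry, function(m) {
    ns <- nutrient_set(m)
    data.frame(model_id = m$model_id, mode = m$mode,
               n_categories = n_categories(m),
               complete = model_is_complete(m),
               n_nutrients = length(ns),
               nutrients = paste(ns, collapse = ";"),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Names of fully specified models in a registry
#' @param registry an `npm_registry`.
#' @return character vector of model ids safe to classify with.
#' @export
complete_models <- function(registry) {
  stopifnot(inherits(registry, "npm_registry"))
  names(registry)[vapply(registry, model_is_complete, logical(1))]
}

#' Look up the criteria a model applies to one of its categories
#'
#' @param model an `npm_model` (threshold mode).
#' @param category_id category name.
#' @return data.frame of criteria (nutrient, comparator, threshold, basis,
#'   optional, todo).
#' @export
category_criteria <- function(model, category_id) {
  stopifnot(inherits(model, "npm_model"), model$mode == "threshold")
  ids <- vapply(model$category_rules, `[[`, character(1), "category_id")
  if (!category_id %in% ids) {
    abort_npm(sprintf("model '%s' has no category '%s'", model$model_id,
                      category_id), "npm_bad_model")
  }
  rule <- model$category_rules[[match(category_id, ids)]]
  do.call(rbind, c(list(NULL), lapply(rule$criteria, function(cr)
    data.frame(nutrient = cr$nutrient, comparator = cr$comparator,
               threshold = cr$threshold, basis = cr$basis,
               optional = cr$optional, todo = cr$todo,
               stringsAsFactors = FALSE))))
}
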
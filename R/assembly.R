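# Dataset assembly: the steps that turn a raw sample of broadcast food
# commercials into an analysable dataset -- exclusion rules, random brand
# representatives, serving-mass-weighted meal averaging, supplementation of
# branded nutrition panels from a generic composition table, and the
# internal validity check between the two data sources.

#' Apply the four exclusion rules
#'
#' Removes records tagged as (1) alcoholic drinks / tea / coffee / chewing
#' gum, (2) broad-range retailers (e.g. supermarkets), (3) baby or toddler
#' foods, (4) weight-loss/-gain shakes. Exclusion classes are explicit
#' input tags, not inferred from names: the judgement of what counts as,
#' say, a broad-range retailer is not machine-decidable, so the rule stays
#' mechanical and auditable.
#'
#' @param raw_foods list of [food_record()]s carrying `exclusion_tags`.
#' @param log optional function called with one message line per exclusion.
#' @return a [commercial_dataset()] of the retained records, unchanged,
#'   with totals recomputed.
#' @export
apply_exclusions <- function(raw_foods, log = NULL) {
  if (inherits(raw_foods, "commercial_dataset")) raw_foods <- raw_foods$foods
  keep <- logical(length(raw_foods))
  for (i in seq_along(raw_foods)) {
    f <- raw_foods[[i]]
    tags <- f$exclusion_tags
    bad <- setdiff(tags, EXCLUSION_TAGS)
    if (length(bad)) {
      abort_npm(sprintf("food '%s': unknown exclusion tag '%s' (known: %s)",
                        f$id, bad[[1L]], paste(EXCLUSION_TAGS, collapse = ", ")),
                "npm_bad_exclusion_tag")
    }
    keep[i] <- length(tags) == 0L
    if (!keep[i] && !is.null(log)) {
      log(sprintf("exclude %s: %s", f$id, paste(tags, collapse = ",")))
    }
  }
  commercial_dataset(raw_foods[keep], provenance = "post-exclusion")
}

#' Serving-mass-weighted meal average
#'
#' Combines the components of an advertised meal (drinks included) into a
#' single per-100 g composition: each nutrient of the result is
#' `sum(value_i * mass_i) / sum(mass_i)`. Drink millilitres are treated as
#' grams (density 1).
#'
#' @param components list of [meal_component()]s, at least one.
#' @param fill policy for a nutrient present in some components only:
#'   `"error"` (default) or `"zero"` (treat absence as 0, e.g. fruit/veg
#'   content of a plain drink).
#' @return a [nutrient_composition()]; the attribute `serving_size_g`
#'   carries the total meal mass.
#' @export
compose_meal <- function(components, fill = c("error", "zero")) {
  fill <- match.arg(fill)
  if (!length(components)) {
    abort_npm("compose_meal needs at least one component", "npm_bad_meal")
  }
  for (cm in components) stopifnot(inherits(cm, "meal_component"))
  mass <- vapply(components, `[[`, numeric(1), "serving_size_g")
  if (sum(mass) <= 0) abort_npm("zero total meal mass", "npm_bad_meal")

  vals <- vapply(components, function(cm) cm$nutrients$values,
                 numeric(length(NUTRIENT_FIELDS)))
  vals <- matrix(vals, nrow = length(NUTRIENT_FIELDS),
                 dimnames = list(NUTRIENT_FIELDS, NULL))
  out <- stats::setNames(rep(NA_real_, length(NUTRIENT_FIELDS)),
                         NUTRIENT_FIELDS)
  for (nm in NUTRIENT_FIELDS) {
    present <- !is.na(vals[nm, ])
    if (!any(present)) next
    if (!all(present)) {
      if (fill == "error") {
        abort_npm(sprintf(
          "nutrient '%s' present in some meal components but not all; supply fill = \"zero\" or supplement first",
          nm), "npm_partial_nutrient")
      }
      vals[nm, !present] <- 0
    }
    out[[nm]] <- sum(vals[nm, ] * mass) / sum(mass)
  }
  fm <- unique(vapply(components, function(cm) cm$nutrients$fibre_method,
                      character(1)))
  res <- nutrient_composition(
    as.list(out[!is.na(out)]),
    fibre_method = if (length(fm) == 1L) fm else "NSP",
    micronutrient_flags = Reduce(union, lapply(components, function(cm)
      cm$nutrients$micronutrient_flags))
  )
  attr(res, "serving_size_g") <- sum(mass)
  res
}

#' Select one product to represent a brand
#'
#' Brands advertised as a range (e.g. a pot snack available in 12 flavours)
#' are represented by a single product drawn uniformly at random, with an
#' explicit seed so the draw is reproducible.
#'
#' @param products non-empty list of [food_record()]s in the range.
#' @param seed integer seed for the draw.
#' @return the selected `food_record`, with attribute `selection_note`
#'   recording the draw.
#' @export
select_brand_representative <- function(products, seed) {
  if (!length(products)) {
    abort_npm("cannot select a representative from an empty product range",
              "npm_bad_brand")
  }
  stopifnot(is_scalar_number(seed))
  for (p in products) stopifnot(inherits(p, "food_record"))
  idx <- withr_seed(seed, sample.int(length(products), 1L))
  out <- products[[idx]]
  attr(out, "selection_note") <- sprintf(
    "selected product %d of %d (seed %d)", idx, length(products),
    as.integer(seed))
  out
}

# evaluate expr under a local RNG seed without disturbing the caller's RNG
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Fill absent branded nutrients from a generic composition
#'
#' Branded values always take precedence; only absent fields are filled
#' from the generic table entry for a similar food. Fields absent in both
#' are an error when listed in `required` -- a food must be complete for
#' every nutrient its models will read before classification.
#'
#' @param branded [nutrient_composition()] from web site / packaging.
#' @param generic [nutrient_composition()] from the generic table.
#' @param required nutrient names that must be present after
#'   supplementation; defaults to the union of fields present in either.
#' @return a `nutrient_composition`; attribute `filled` names the fields
#'   taken from the generic source (non-empty means data_source "mixed").
#' @export
supplement_nutrients <- function(branded, generic,
                                 required = NULL) {
  stopifnot(inherits(branded, "nutrient_composition"),
            inherits(generic, "nutrient_composition"))
  out <- branded$values
  filled <- character()
  for (nm in NUTRIENT_FIELDS) {
    if (is.na(out[[nm]]) && !is.na(generic$values[[nm]])) {
      out[[nm]] <- generic$values[[nm]]
      filled <- c(filled, nm)
    }
  }
  if (!is.null(required)) {
    still_missing <- required[vapply(required, function(nm) is.na(out[[nm]]),
                                     logical(1))]
    if (length(still_missing)) {
      abort_npm(sprintf("nutrient(s) absent in both branded and generic data: %s",
                        paste(still_missing, collapse = ", ")),
                "npm_missing_nutrient")
    }
  }
  res <- nutrient_composition(as.list(out[!is.na(out)]),
                              fibre_method = branded$fibre_method,
                              micronutrient_flags = union(
                                branded$micronutrient_flags,
                                generic$micronutrient_flags))
  attr(res, "filled") <- filled
  res
}

#' Supplement a food record and track provenance
#'
#' Convenience wrapper around [supplement_nutrients()] that updates the
#' record's `data_source` to `"mixed"` when any field was filled.
#'
#' @param food a [food_record()].
#' @param generic generic [nutrient_composition()].
#' @param required see [supplement_nutrients()].
#' @param log optional function receiving one line per filled nutrient.
#' @return the updated `food_record`.
#' @export
supplement_food <- function(food, generic, required = NULL, log = NULL) {
  stopifnot(inherits(food, "food_record"))
  nut <- supplement_nutrients(food$nutrients, generic, required = required)
  filled <- attr(nut, "filled")
  food$nutrients <- nut
  if (length(filled)) {
    food$data_source <- "mixed"
    if (!is.null(log)) {
      log(sprintf("supplement %s: %s from generic table", food$id,
                  paste(filled, collapse = ",")))
    }
  }
  food
}

#' Branded-vs-generic validity correlation
#'
#' Pearson correlation between nutrient values extracted from web
#' sites/packaging and values for the matched generic food, plus the
#' least-squares slope of generic on branded (slope > 1 means the generic
#' table tends to overestimate the branded value; < 1 underestimate).
#'
#' @param branded,generic paired numeric vectors (same foods, same
#'   nutrient), at least 3 finite pairs.
#' @param nutrient label carried into the result.
#' @return list with `nutrient`, `n`, `r`, `slope`, `intercept`;
#'   `r`/`slope` are `NA` with `degenerate = TRUE` when either series has
#'   zero variance.
#' @export
validity_correlation <- function(branded, generic, nutrient = "") {
  if (length(branded) != length(generic)) {
    abort_npm("branded and generic series must have equal length",
              "npm_bad_validity")
  }
  ok <- is.finite(branded) & is.finite(generic)
  x <- branded[ok]; y <- generic[ok]
  if (length(x) < 3L) {
    abort_npm("validity correlation needs at least 3 finite pairs",
              "npm_bad_validity")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(list(nutrient = nutrient, n = length(x), r = NA_real_,
                slope = NA_real_, intercept = NA_real_, degenerate = TRUE))
  }
  fit <- stats::lm(y ~ x)
  list(nutrient = nutrient, n = length(x),
       r = stats::cor(x, y),
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       degenerate = FALSE)
}
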
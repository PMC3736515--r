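# Agreement statistics: commercial-weighted approval proportions with
# food-based binomial confidence intervals, pairwise Cohen's kappa on
# commercial-weighted 2x2 tables, food-guide category breakdowns, and the
# per-food count of approving models.

#' Approval summary for one model
#'
#' Point estimates at two levels: the share of distinct foods approved and
#' the share of commercials approved (each food weighted by its broadcast
#' count). Confidence intervals use the normal-approximation binomial with
#' n = number of foods, applied to both point estimates: repeated
#' broadcasts of the same commercial carry no independent classification
#' information, so the standard error is based on foods, not commercials.
#' Intervals are clipped to \[0, 100\].
#'
#' @param approved logical vector, one flag per food.
#' @param weights commercial counts per food (same order); or pass
#'   `dataset` instead.
#' @param dataset optional [commercial_dataset()] supplying the weights.
#' @param model_id label carried into the result.
#' @param conf_z normal quantile for the interval (1.96 for 95%).
#' @return object of class `approval_summary`: counts, percentages and
#'   `(lo, hi)` bounds for both levels.
#' @export
approval_summary <- function(approved, weights = NULL, dataset = NULL,
                             model_id = "", conf_z = 1.96) {
  if (!is.null(dataset)) {
    stopifnot(inherits(dataset, "commercial_dataset"))
    weights <- commercial_weights(dataset)
  }
  if (is.null(weights)) weights <- rep(1, length(approved))
  if (!length(approved)) {
    abort_npm("approval_summary needs at least one classified food",
              "npm_bad_summary")
  }
  if (anyNA(approved)) {
    abort_npm("approval_summary: unclassified food (NA approved flag)",
              "npm_bad_summary")
  }
  if (length(weights) != length(approved)) {
    abort_npm("approved flags and weights differ in length",
              "npm_bad_summary")
  }
  n <- length(approved)
  pf <- mean(approved) * 100
  pc <- sum(weights[approved]) / sum(weights) * 100
  h <- conf_z * sqrt(pf / 100 * (1 - pf / 100) / n) * 100
  clip <- function(x) pmin(pmax(x, 0), 100)
  structure(list(
    model_id = model_id, n_foods_total = n,
    n_commercials_total = sum(weights),
    n_foods_approved = sum(approved),
    pct_foods_approved = pf,
    pct_foods_ci = c(lo = clip(pf - h), hi = clip(pf + h)),
    pct_commercials_approved = pc,
    pct_commercials_ci = c(lo = clip(pc - h), hi = clip(pc + h)),
    half_width = h), class = "approval_summary")
}

#' @export
print.approval_summary <- function(x, ...) {
  cat(sprintf(
    "<approval_summary> %s: %d/%d foods = %.1f%% (%.1f, %.1f); commercials %.1f%% (%.1f, %.1f)\n",
    x$model_id, x$n_foods_approved, x$n_foods_total, x$pct_foods_approved,
    x$pct_foods_ci[["lo"]], x$pct_foods_ci[["hi"]],
    x$pct_commercials_approved, x$pct_commercials_ci[["lo"]],
    x$pct_commercials_ci[["hi"]]))
  invisible(x)
}

#' Cohen's kappa for two weighted binary classifications
#'
#' Builds the 2x2 contingency table with each food contributing its
#' commercial count as a frequency weight, then
#' `kappa = (po - pe) / (1 - pe)` with `po` the weighted agreement
#' fraction and `pe` the chance agreement from the marginals. Perfect
#' agreement returns exactly 1. When the marginals force `pe = 1` with
#' imperfect agreement the statistic is undefined and `NA` is returned
#' with attribute `undefined = TRUE`.
#'
#' @param a,b logical approval vectors over the same foods.
#' @param weights non-negative frequency weights (default all 1).
#' @return scalar kappa in \[-1, 1\] (or `NA` when undefined).
#' @export
cohens_kappa <- function(a, b, weights = rep(1, length(a))) {
  if (length(a) != length(b) || length(a) != length(weights)) {
    abort_npm("kappa inputs must have equal length", "npm_bad_kappa")
  }
  if (anyNA(a) || anyNA(b)) {
    abort_npm("kappa inputs must not contain NA", "npm_bad_kappa")
  }
  w <- sum(weights)
  if (w <= 0) abort_npm("zero total weight", "npm_bad_kappa")
  w11 <- sum(weights[a & b]); w00 <- sum(weights[!a & !b])
  w10 <- sum(weights[a & !b]); w01 <- sum(weights[!a & b])
  po <- (w11 + w00) / w
  if (po == 1) return(1)
  pa1 <- (w11 + w10) / w; pb1 <- (w11 + w01) / w
  pe <- pa1 * pb1 + (1 - pa1) * (1 - pb1)
  if (pe == 1) {
    return(structure(NA_real_, undefined = TRUE))
  }
  (po - pe) / (1 - pe)
}

KAPPA_BANDS <- data.frame(
  band = c("less than fair", "fair", "moderate", "good", "very good"),
  stars = c("", "*", "**", "***", "****"),
  stringsAsFactors = FALSE
)

#' Interpretation band for a kappa value
#'
#' The published cut points: 0.21-0.40 "fair", 0.41-0.60 "moderate",
#' 0.61-0.80 "good"; below 0.21 is less than fair and above 0.80 very
#' good. A boundary value belongs to the band whose printed range names
#' it (0.40 is "fair", 0.60 "moderate", 0.80 "good").
#'
#' @param kappa numeric vector in \[-1, 1\].
#' @return character vector of band labels.
#' @export
interpret_kappa <- function(kappa) {
  stopifnot(all(is.na(kappa) | (kappa >= -1 & kappa <= 1)))
  vapply(kappa, function(k) {
    if (is.na(k)) return(NA_character_)
    if (k > 0.80) "very good"
    else if (k > 0.60) "good"
    else if (k > 0.40) "moderate"
    else if (k >= 0.21) "fair"
    else "less than fair"
  }, character(1))
}

kappa_stars <- function(band) {
  ifelse(is.na(band), "",
         KAPPA_BANDS$stars[match(band, KAPPA_BANDS$band)])
}

#' Pairwise kappa matrix across models
#'
#' @param cls a `classification_set` from [classify_dataset()], or a
#'   logical foods x models matrix.
#' @param weights commercial counts (taken from `cls` when it is a
#'   classification set).
#' @return object of class `agreement_matrix`: symmetric `kappa` matrix
#'   with unit diagonal, parallel `band` matrix, and the weight basis.
#' @export
agreement_matrix <- function(cls, weights = NULL) {
  if (inherits(cls, "classification_set")) {
    m <- cls$approved
    if (is.null(weights)) weights <- cls$weights
  } else {
    m <- cls
  }
  stopifnot(is.matrix(m), is.logical(m))
  if (is.null(weights)) weights <- rep(1, nrow(m))
  models <- colnames(m)
  k <- matrix(1, ncol(m), ncol(m), dimnames = list(models, models))
  for (i in seq_len(ncol(m))) {
    for (j in seq_len(ncol(m))) {
      if (j > i) {
        k[i, j] <- k[j, i] <- cohens_kappa(m[, i], m[, j], weights)
      }
    }
  }
  band <- matrix(interpret_kappa(as.vector(k)), ncol(m), ncol(m),
                 dimnames = dimnames(k))
  structure(list(models = models, kappa = k, band = band,
                 weight_basis = "commercial counts as frequency weights"),
            class = "agreement_matrix")
}

#' @export
print.agreement_matrix <- function(x, digits = 2, ...) {
  cat("<agreement_matrix> pairwise Cohen's kappa,", x$weight_basis, "\n")
  print(round_half_up(x$kappa, digits))
  invisible(x)
}

#' Percentage of commercials approved per food-guide category
#'
#' For each food-guide category (with the fatty/sugary group additionally
#' split into snacks, non-snacks and drinks) and each model:
#' `100 * approved commercial weight / total commercial weight` in the
#' category. A category with zero commercials is undefined (`NA`).
#'
#' @param cls a `classification_set` from [classify_dataset()].
#' @return object of class `category_breakdown`: data.frame `table` with
#'   one row per (category, model), plus `category_weights`.
#' @export
category_breakdown <- function(cls) {
  stopifnot(inherits(cls, "classification_set"))
  foods <- cls$dataset$foods
  cat_of <- vapply(foods, function(f) {
    if (identical(f$food_guide_category, "fatty_sugary")) {
      paste0("fatty_sugary_", f$fatty_sugary_subtag)
    } else {
      f$food_guide_category
    }
  }, character(1))
  w <- cls$weights
  cats <- c(setdiff(FOOD_GUIDE_CATEGORIES, "fatty_sugary"),
            paste0("fatty_sugary_", FATTY_SUGARY_SUBTAGS))
  cats <- cats[cats %in% cat_of]
  rows <- list()
  for (cc in cats) {
    in_cat <- cat_of == cc
    wt <- sum(w[in_cat])
    for (mid in cls$models) {
      appr <- cls$approved[in_cat, mid]
      rows[[length(rows) + 1L]] <- data.frame(
        category = cc, model_id = mid,
        n_foods = sum(in_cat), n_commercials = wt,
        pct_commercials_approved =
          if (wt > 0) sum(w[in_cat][appr]) / wt * 100 else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab,
                 category_weights = tapply(w, cat_of, sum)),
            class = "category_breakdown")
}

#' @export
print.category_breakdown <- function(x, ...) {
  cat("<category_breakdown> % commercials approved by category x model\n")
  wide <- stats::reshape(
    x$table[, c("category", "model_id", "pct_commercials_approved")],
    idvar = "category", timevar = "model_id", direction = "wide")
  names(wide) <- sub("^pct_commercials_approved\\.", "", names(wide))
  print(wide, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Number of models approving each food
#'
#' @param cls a `classification_set` covering all models of interest.
#' @return list with `counts` (named integer vector per food, 0..n
#'   models), `distribution` (data.frame of food and commercial shares by
#'   count), and the commercial-weighted shares at count 0
#'   (`pct_commercials_none`, rejected by every model) and at the maximum
#'   (`pct_commercials_all`).
#' @export
approving_model_count <- function(cls) {
  stopifnot(inherits(cls, "classification_set"))
  if (anyNA(cls$approved)) {
    abort_npm("approving_model_count: missing model result", "npm_bad_summary")
  }
  counts <- rowSums(cls$approved)
  w <- cls$weights
  n_models <- ncol(cls$approved)
  dist <- do.call(rbind, lapply(0:n_models, function(k) {
    sel <- counts == k
    data.frame(n_models_approving = k, n_foods = sum(sel),
               pct_foods = mean(sel) * 100,
               pct_commercials = sum(w[sel]) / sum(w) * 100)
  }))
  list(counts = stats::setNames(as.integer(counts), rownames(cls$approved)),
       distribution = dist,
       pct_commercials_none = dist$pct_commercials[1L],
       pct_commercials_all = dist$pct_commercials[n_models + 1L])
}
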
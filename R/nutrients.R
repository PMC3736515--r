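# Nutrient composition: named per-100 g quantities, any of which may be
# absent (NA). Absence is meaningful -- the engine refuses to classify a
# food that lacks a nutrient its model needs, mirroring the discipline of
# supplementing branded data from a generic composition table rather than
# silently passing or failing.

#' Nutrient field names understood by the package
#'
#' All quantities are per 100 g of food as consumed (drinks: per 100 ml,
#' density 1). `fruit_veg_nut_pct` is the fruit/vegetable/nut percentage
#' (0-100) used by points-based scoring.
#'
#' @export
NUTRIENT_FIELDS <- c(
  "energy_kJ", "energy_kcal", "total_fat_g", "saturated_fat_g",
  "trans_fat_g", "cholesterol_mg", "total_sugar_g", "added_sugar_g",
  "sodium_mg", "protein_g", "fibre_g", "fruit_veg_nut_pct"
)

# kcal contributed per gram, used for percent-of-energy criterion bases
ENERGY_FACTORS_KCAL_PER_G <- c(
  total_fat_g = 9, saturated_fat_g = 9, trans_fat_g = 9,
  total_sugar_g = 4, added_sugar_g = 4, protein_g = 4, fibre_g = 2
)

KJ_PER_KCAL <- 4.184

#' Create a nutrient composition
#'
#' @param ... named per-100 g quantities from [NUTRIENT_FIELDS]; omitted
#'   fields are recorded as absent (`NA`).
#' @param fibre_method fibre assay convention, `"NSP"` (Englyst,
#'   non-starch polysaccharide) or `"AOAC"`; points tables carry separate
#'   fibre thresholds for the two assays.
#' @param micronutrient_flags character vector of qualifying-micronutrient
#'   labels (e.g. `"vitamin_c_10pct_dv"`); used by models with a
#'   vitamins/minerals component.
#' @return an object of class `nutrient_composition`.
#' @examples
#' nutrient_composition(energy_kJ = 1500, total_sugar_g = 20, sodium_mg = 500)
#' @export
nutrient_composition <- function(..., fibre_method = c("NSP", "AOAC"),
                                 micronutrient_flags = character()) {
  fibre_method <- match.arg(fibre_method)
  vals <- list(...)
  if (length(vals) == 1L && is.null(names(vals)) && is.list(vals[[1L]])) {
    vals <- vals[[1L]]
  }
  unknown <- setdiff(names(vals), NUTRIENT_FIELDS)
  if (length(unknown)) {
    abort_npm(sprintf("unknown nutrient field(s): %s",
                      paste(unknown, collapse = ", ")),
              "npm_bad_nutrient")
  }
  x <- stats::setNames(rep(NA_real_, length(NUTRIENT_FIELDS)), NUTRIENT_FIELDS)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.null(v) && !(length(v) == 1L && is.na(v))) {
      if (!is_scalar_number(v)) {
        abort_npm(sprintf("nutrient '%s' must be a single finite number", nm),
                  "npm_bad_nutrient")
      }
      x[[nm]] <- as.numeric(v)
    }
  }
  out <- structure(
    list(values = x, fibre_method = fibre_method,
         micronutrient_flags = as.character(micronutrient_flags)),
    class = "nutrient_composition"
  )
  validate_nutrients(out)
  out
}

validate_nutrients <- function(nc) {
  v <- nc$values
  neg <- names(v)[!is.na(v) & v < 0]
  if (length(neg)) {
    abort_npm(sprintf("negative nutrient value(s): %s",
                      paste(neg, collapse = ", ")), "npm_bad_nutrient")
  }
  if (!is.na(v[["fruit_veg_nut_pct"]]) && v[["fruit_veg_nut_pct"]] > 100) {
    abort_npm("fruit_veg_nut_pct exceeds 100", "npm_bad_nutrient")
  }
  kj <- v[["energy_kJ"]]; kcal <- v[["energy_kcal"]]
  if (!is.na(kj) && !is.na(kcal) && kcal > 0) {
    if (abs(kj - KJ_PER_KCAL * kcal) > 0.02 * KJ_PER_KCAL * kcal) {
      abort_npm(sprintf(
        "energy fields inconsistent: %g kJ vs %g kcal (expect kJ = 4.184 x kcal within 2%%)",
        kj, kcal), "npm_bad_nutrient")
    }
  }
  invisible(nc)
}

#' @export
print.nutrient_composition <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat("<nutrient_composition> per 100 g, fibre method", x$fibre_method, "\n")
  if (length(v)) {
    cat(paste(sprintf("  %s: %g", names(v), v), collapse = "\n"), "\n")
  } else {
    cat("  (all fields absent)\n")
  }
  if (length(x$micronutrient_flags)) {
    cat("  micronutrients:", paste(x$micronutrient_flags, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Get one nutrient value, NA if absent
#' @param nc a `nutrient_composition`.
#' @param field a name from [NUTRIENT_FIELDS].
#' @return scalar numeric, `NA` when absent.
#' @export
nutrient_value <- function(nc, field) {
  stopifnot(inherits(nc, "nutrient_composition"))
  if (!field %in% NUTRIENT_FIELDS) {
    abort_npm(sprintf("unknown nutrient field '%s'", field), "npm_bad_nutrient")
  }
  nc$values[[field]]
}

# energy in kcal, deriving from kJ when the kcal field is absent
energy_kcal_of <- function(nc) {
  kcal <- nc$values[["energy_kcal"]]
  if (!is.na(kcal)) return(kcal)
  kj <- nc$values[["energy_kJ"]]
  if (!is.na(kj)) return(kj / KJ_PER_KCAL)
  NA_real_
}

# energy in kJ, deriving from kcal when the kJ field is absent
energy_kj_of <- function(nc) {
  kj <- nc$values[["energy_kJ"]]
  if (!is.na(kj)) return(kj)
  kcal <- nc$values[["energy_kcal"]]
  if (!is.na(kcal)) return(kcal * KJ_PER_KCAL)
  NA_real_
}
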
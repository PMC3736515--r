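# Food records and the commercial dataset container. A record is one
# advertised product, brand representative, or averaged meal, with its
# per-100 g nutrients and the number of times its commercial was broadcast
# in the sampling window.

#' Closed list of UK food-guide categories
#'
#' The seven "Balance of Good Health" groups used for stratified reporting;
#' the fatty/sugary group is further split into snacks, non-snacks and
#' drinks via `fatty_sugary_subtag`.
#' @export
FOOD_GUIDE_CATEGORIES <- c(
  "bread_cereals_potatoes", "fruit_veg", "meat_fish_alternatives",
  "milk_dairy", "fatty_sugary", "composite", "miscellaneous"
)

#' @rdname FOOD_GUIDE_CATEGORIES
#' @export
FATTY_SUGARY_SUBTAGS <- c("snack", "not_snack", "drink")

EXCLUSION_TAGS <- c("alcohol_tea_coffee_gum", "broad_range_retailer",
                    "baby_toddler_food", "weight_shake")

DATA_SOURCES <- c("web_site", "packaging", "generic_table", "mixed")

#' Create a food record
#'
#' @param id opaque identifier, unique within a dataset.
#' @param name free-text product name.
#' @param nutrients a [nutrient_composition()].
#' @param commercial_count non-negative integer: broadcasts observed.
#' @param food_guide_category one of [FOOD_GUIDE_CATEGORIES].
#' @param fatty_sugary_subtag for `fatty_sugary` foods, one of
#'   [FATTY_SUGARY_SUBTAGS]; `NA` otherwise.
#' @param commercial_kind `"single_item"`, `"brand"` or `"meal"`.
#' @param serving_size_g declared serving in grams (drinks: ml, density 1);
#'   required only when a per-serving criterion will be evaluated.
#' @param is_drink logical; drives food/drink category splits.
#' @param model_category_tags character vector of tags consumed by
#'   per-model category matching (e.g. `"breakfast_cereal"`, `"milk"`).
#' @param data_source provenance of the nutrition data.
#' @param exclusion_tags tags identifying records the assembly stage must
#'   drop (see [apply_exclusions()]); empty for retained foods.
#' @return an object of class `food_record`.
#' @export
food_record <- function(id, name = id, nutrients = nutrient_composition(),
                        commercial_count = 1L,
                        food_guide_category = "miscellaneous",
                        fatty_sugary_subtag = NA_character_,
                        commercial_kind = c("single_item", "brand", "meal"),
                        serving_size_g = NA_real_, is_drink = FALSE,
                        model_category_tags = character(),
                        data_source = c("web_site", "packaging",
                                        "generic_table", "mixed"),
                        exclusion_tags = character()) {
  commercial_kind <- match.arg(commercial_kind)
  data_source <- match.arg(data_source)
  stopifnot(inherits(nutrients, "nutrient_composition"))
  if (!is_scalar_number(commercial_count) || commercial_count < 0 ||
      commercial_count != round(commercial_count)) {
    abort_npm(sprintf("food '%s': commercial_count must be a non-negative integer", id),
              "npm_bad_record")
  }
  if (!food_guide_category %in% FOOD_GUIDE_CATEGORIES) {
    abort_npm(sprintf("food '%s': unknown food_guide_category '%s'",
                      id, food_guide_category), "npm_bad_record")
  }
  if (identical(food_guide_category, "fatty_sugary")) {
    if (is.na(fatty_sugary_subtag) ||
        !fatty_sugary_subtag %in% FATTY_SUGARY_SUBTAGS) {
      abort_npm(sprintf("food '%s': fatty_sugary foods need a subtag (snack/not_snack/drink)", id),
                "npm_bad_record")
    }
  }
  if (!is.na(serving_size_g) && serving_size_g <= 0) {
    abort_npm(sprintf("food '%s': serving_size_g must be positive", id),
              "npm_bad_record")
  }
  stopifnot(is_flag(is_drink))
  structure(
    list(id = as.character(id), name = as.character(name),
         commercial_kind = commercial_kind, nutrients = nutrients,
         serving_size_g = as.numeric(serving_size_g), is_drink = is_drink,
         food_guide_category = food_guide_category,
         fatty_sugary_subtag = as.character(fatty_sugary_subtag),
         model_category_tags = as.character(model_category_tags),
         commercial_count = as.integer(commercial_count),
         data_source = data_source,
         exclusion_tags = as.character(exclusion_tags)),
    class = "food_record"
  )
}

#' @export
print.food_record <- function(x, ...) {
  cat(sprintf("<food_record> %s (%s, %s; %d commercials)\n",
              x$id, x$food_guide_category,
              if (x$is_drink) "drink" else "food", x$commercial_count))
  invisible(x)
}

#' Create a meal component
#'
#' One element of an advertised meal (burger, fries, drink, ...) prior to
#' serving-mass-weighted averaging by [compose_meal()].
#'
#' @param nutrients a [nutrient_composition()].
#' @param serving_size_g component serving mass in grams (> 0).
#' @param role `"food"` or `"drink"`; drinks are included in the average.
#' @return an object of class `meal_component`.
#' @export
meal_component <- function(nutrients, serving_size_g, role = c("food", "drink")) {
  role <- match.arg(role)
  stopifnot(inherits(nutrients, "nutrient_composition"))
  if (!is_scalar_number(serving_size_g) || serving_size_g <= 0) {
    abort_npm("meal component serving_size_g must be a positive number",
              "npm_bad_record")
  }
  structure(list(nutrients = nutrients, serving_size_g = serving_size_g,
                 role = role),
            class = "meal_component")
}

#' Create a commercial dataset
#'
#' @param foods list of [food_record()]s.
#' @param provenance free-text provenance note (seed, source, stage).
#' @return object of class `commercial_dataset`; `total_commercials` is
#'   always recomputed as the sum of per-food counts.
#' @export
commercial_dataset <- function(foods, provenance = "") {
  stopifnot(is.list(foods))
  for (f in foods) {
    if (!inherits(f, "food_record")) {
      abort_npm("all dataset elements must be food_record objects",
                "npm_bad_record")
    }
  }
  ids <- vapply(foods, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    abort_npm(sprintf("duplicate food id(s): %s",
                      paste(unique(ids[duplicated(ids)]), collapse = ", ")),
              "npm_bad_record")
  }
  structure(
    list(foods = foods,
         total_commercials = sum(vapply(foods, `[[`, integer(1),
                                        "commercial_count")),
         provenance = provenance),
    class = "commercial_dataset"
  )
}

#' @export
print.commercial_dataset <- function(x, ...) {
  cat(sprintf("<commercial_dataset> %d foods, %d commercials\n",
              length(x$foods), x$total_commercials))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
length.commercial_dataset <- function(x) length(x$foods)

#' Per-food commercial counts
#' @param dataset a `commercial_dataset`.
#' @return named integer vector of broadcast counts.
#' @export
commercial_weights <- function(dataset) {
  stopifnot(inherits(dataset, "commercial_dataset"))
  stats::setNames(vapply(dataset$foods, `[[`, integer(1), "commercial_count"),
                  vapply(dataset$foods, `[[`, character(1), "id"))
}

# ---- tabular round trip -----------------------------------------------

FOOD_TABLE_COLUMNS <- c(
  "id", "name", "commercial_kind", "serving_size_g", "is_drink",
  "food_guide_category", "fatty_sugary_subtag", "model_category_tags",
  "commercial_count", "data_source", "exclusion_tags", "fibre_method",
  "micronutrient_flags", NUTRIENT_FIELDS
)

#' @export
as.data.frame.commercial_dataset <- function(x, ...) {
  rows <- lapply(x$foods, function(f) {
    v <- as.list(f$nutrients$values)
    data.frame(
      id = f$id, name = f$name, commercial_kind = f$commercial_kind,
      serving_size_g = f$serving_size_g, is_drink = f$is_drink,
      food_guide_category = f$food_guide_category,
      fatty_sugary_subtag = f$fatty_sugary_subtag,
      model_category_tags = paste(f$model_category_tags, collapse = ";"),
      commercial_count = f$commercial_count, data_source = f$data_source,
      exclusion_tags = paste(f$exclusion_tags, collapse = ";"),
      fibre_method = f$nutrients$fibre_method,
      micronutrient_flags = paste(f$nutrients$micronutrient_flags,
                                  collapse = ";"),
      v, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(FOOD_TABLE_COLUMNS)), FOOD_TABLE_COLUMNS))
  }
  rownames(out) <- NULL
  out
}

split_tags <- function(s) {
  if (is.na(s) || !nzchar(s)) character() else strsplit(s, ";", fixed = TRUE)[[1L]]
}

food_record_from_row <- function(row) {
  nut <- row[NUTRIENT_FIELDS]
  nut <- nut[!vapply(nut, function(v) is.na(v), logical(1))]
  subtag <- row$fatty_sugary_subtag
  if (!is.na(subtag) && !nzchar(subtag)) subtag <- NA_character_
  food_record(
    id = row$id, name = if (is.na(row$name)) row$id else row$name,
    nutrients = nutrient_composition(
      nut, fibre_method = if (is.na(row$fibre_method)) "NSP" else row$fibre_method,
      micronutrient_flags = split_tags(row$micronutrient_flags)),
    commercial_count = row$commercial_count,
    food_guide_category = row$food_guide_category,
    fatty_sugary_subtag = subtag,
    commercial_kind = row$commercial_kind,
    serving_size_g = row$serving_size_g, is_drink = isTRUE(row$is_drink),
    model_category_tags = split_tags(row$model_category_tags),
    data_source = row$data_source,
    exclusion_tags = split_tags(row$exclusion_tags)
  )
}

#' Read a food table from CSV
#'
#' One row per food, header mandatory, absent nutrients as empty cells.
#' Column names follow the `food_record` fields; list-valued fields
#' (`model_category_tags`, `exclusion_tags`, `micronutrient_flags`) are
#' semicolon-separated.
#'
#' @param path CSV file path.
#' @param permissive allow (and ignore) unknown columns; by default unknown
#'   columns are rejected so typos cannot silently drop data.
#' @param provenance provenance note attached to the dataset.
#' @return a [commercial_dataset()].
#' @export
read_food_table <- function(path, permissive = FALSE, provenance = path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  unknown <- setdiff(names(df), FOOD_TABLE_COLUMNS)
  if (length(unknown) && !permissive) {
    abort_npm(sprintf("unknown column(s) in %s: %s (set permissive = TRUE to ignore)",
                      path, paste(unknown, collapse = ", ")), "npm_bad_table")
  }
  missing <- setdiff(c("id", "food_guide_category", "commercial_count"),
                     names(df))
  if (length(missing)) {
    abort_npm(sprintf("food table %s lacks required column(s): %s",
                      path, paste(missing, collapse = ", ")), "npm_bad_table")
  }
  for (col in setdiff(FOOD_TABLE_COLUMNS, names(df))) {
    df[[col]] <- if (col %in% c(NUTRIENT_FIELDS, "serving_size_g")) {
      NA_real_
    } else if (col == "is_drink") FALSE
    else if (col == "commercial_kind") "single_item"
    else if (col == "data_source") "web_site"
    else if (col == "fibre_method") "NSP"
    else NA_character_
  }
  if (is.character(df$is_drink)) {
    df$is_drink <- toupper(trimws(df$is_drink)) %in% c("TRUE", "T", "1", "YES")
  }
  foods <- lapply(seq_len(nrow(df)), function(i) food_record_from_row(df[i, ]))
  commercial_dataset(foods, provenance = provenance)
}

#' Write a food table to CSV
#' @param dataset a [commercial_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_food_table <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a generic food-composition table
#'
#' CSV keyed by generic-food name, one row per generic food, nutrient
#' columns as in [NUTRIENT_FIELDS]. Used to supplement branded data.
#'
#' @param path CSV file path.
#' @param permissive allow unknown columns.
#' @return named list of [nutrient_composition()]s keyed by `name`.
#' @export
read_generic_table <- function(path, permissive = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  allowed <- c("name", "fibre_method", NUTRIENT_FIELDS)
  unknown <- setdiff(names(df), allowed)
  if (length(unknown) && !permissive) {
    abort_npm(sprintf("unknown column(s) in %s: %s", path,
                      paste(unknown, collapse = ", ")), "npm_bad_table")
  }
  if (!"name" %in% names(df)) {
    abort_npm(sprintf("generic table %s lacks a 'name' column", path),
              "npm_bad_table")
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    nut <- row[intersect(NUTRIENT_FIELDS, names(df))]
    nut <- nut[!vapply(nut, is.na, logical(1))]
    nutrient_composition(
      nut,
      fibre_method = if (!"fibre_method" %in% names(df) ||
                         is.na(row$fibre_method)) "NSP" else row$fibre_method)
  })
  stats::setNames(out, df$name)
}
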
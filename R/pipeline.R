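# End-to-end orchestration: assembly -> classification (all complete
# models x all foods) -> approval summaries -> kappa matrix -> category
# breakdown -> approving-model counts, with CSV report outputs and a
# line-oriented run log. Re-running with an identical configuration and
# inputs reproduces byte-identical outputs (no timestamps; the seed is
# the only run identity echoed into provenance).

#' Pipeline run configuration
#'
#' @param input path to a food-table CSV, or `NULL` to generate a
#'   synthetic dataset from `synthetic` (the default).
#' @param synthetic a [generator_config()]; built from `seed` when absent.
#' @param models_dir model registry directory (default: shipped models).
#' @param exclude_models model ids to drop from the run.
#' @param model_options named list of model option overrides (e.g.
#'   `list(danish_sodium_considered = TRUE)`).
#' @param out_dir output directory for the report CSVs; created if absent.
#' @param seed integer seed used for the synthetic dataset and recorded in
#'   every output.
#' @param verbose print progress lines.
#' @return object of class `run_config`.
#' @export
run_config <- function(input = NULL, synthetic = NULL,
                       models_dir = system.file("models",
                                                package = "npmagree"),
                       exclude_models = character(),
                       model_options = list(), out_dir = NULL,
                       seed = 1L, verbose = FALSE) {
  if (!is.null(input) && !file.exists(input)) {
    abort_npm(sprintf("input food table does not exist: %s", input),
              "npm_bad_config")
  }
  if (!dir.exists(models_dir)) {
    abort_npm(sprintf("models_dir does not exist: %s", models_dir),
              "npm_bad_config")
  }
  if (is.null(synthetic) && is.null(input)) {
    synthetic <- generator_config(seed = seed)
  }
  structure(list(input = input, synthetic = synthetic,
                 models_dir = models_dir,
                 exclude_models = exclude_models,
                 model_options = model_options, out_dir = out_dir,
                 seed = as.integer(seed), verbose = verbose),
            class = "run_config")
}

write_report_csv <- function(df, path, seed) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# seed: %d", seed), con)
  utils::write.csv(df, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Approval summary table (one row per model)
#' @param summaries list of `approval_summary` objects.
#' @param digits decimal places for reported percentages (half-up,
#'   applied at output only).
#' @return data.frame mirroring the published per-model approval table.
#' @export
approval_table <- function(summaries, digits = 1) {
  do.call(rbind, lapply(summaries, function(s) data.frame(
    model_id = s$model_id,
    n_foods_approved = s$n_foods_approved,
    pct_foods_approved = round_half_up(s$pct_foods_approved, digits),
    pct_foods_ci_lo = round_half_up(s$pct_foods_ci[["lo"]], digits),
    pct_foods_ci_hi = round_half_up(s$pct_foods_ci[["hi"]], digits),
    pct_commercials_approved =
      round_half_up(s$pct_commercials_approved, digits),
    pct_commercials_ci_lo = round_half_up(s$pct_commercials_ci[["lo"]], digits),
    pct_commercials_ci_hi = round_half_up(s$pct_commercials_ci[["hi"]], digits),
    stringsAsFactors = FALSE, row.names = NULL)))
}

#' Kappa matrix as an upper-triangular table with band stars
#' @param am an `agreement_matrix`.
#' @param digits decimal places (half-up, output only).
#' @return data.frame, models as rows/columns, cells "kappa stars".
#' @export
kappa_table <- function(am, digits = 2) {
  stopifnot(inherits(am, "agreement_matrix"))
  k <- am$kappa
  n <- length(am$models)
  out <- matrix("", n, n, dimnames = dimnames(k))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) {
        out[i, j] <- trimws(sprintf(
          "%.*f%s", digits, round_half_up(k[i, j], digits),
          kappa_stars(am$band[i, j])))
      }
    }
  }
  data.frame(model_id = am$models, out, check.names = FALSE,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Run the full comparison pipeline
#'
#' @param config a [run_config()].
#' @return invisibly, a `pipeline_result` list: `dataset`,
#'   `classifications` (a `classification_set`), `summaries`,
#'   `approval_table`, `kappa` (`agreement_matrix`), `breakdown`,
#'   `model_counts`, `models`, `log` (character lines). When
#'   `config$out_dir` is set the report CSVs and run log are written
#'   there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character()
  logf <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    if (config$verbose) message(line)
  }
  logf("stage=config seed=%d", config$seed)

  registry <- load_model_registry(config$models_dir)
  models <- setdiff(names(registry), config$exclude_models)
  incomplete <- models[!vapply(registry[models], model_is_complete,
                               logical(1))]
  if (length(incomplete)) {
    logf("stage=registry action=auto-exclude incomplete=%s",
         paste(incomplete, collapse = ","))
    models <- setdiff(models, incomplete)
  }
  if (!length(models)) {
    abort_npm("no complete models left to run; complete the TODO thresholds or adjust exclusions",
              "npm_bad_config")
  }
  logf("stage=registry models=%s", paste(models, collapse = ","))

  if (!is.null(config$input)) {
    raw <- read_food_table(config$input)
    dataset <- apply_exclusions(raw$foods,
                                log = function(m) logf("stage=exclusion %s", m))
  } else {
    dataset <- generate_dataset(config$synthetic)
    logf("stage=simulate n_foods=%d total_commercials=%d",
         length(dataset$foods), dataset$total_commercials)
  }

  cls <- classify_dataset(dataset, registry, models = models,
                          options = config$model_options)
  for (mid in models) {
    logf("stage=classify model=%s approved=%d/%d", mid,
         sum(cls$approved[, mid]), nrow(cls$approved))
  }

  summaries <- lapply(models, function(mid)
    approval_summary(cls$approved[, mid], weights = cls$weights,
                     model_id = mid))
  names(summaries) <- models
  atab <- approval_table(summaries)
  am <- agreement_matrix(cls)
  bd <- category_breakdown(cls)
  mc <- approving_model_count(cls)

  per_food <- data.frame(
    food_id = rownames(cls$approved),
    food_guide_category = vapply(dataset$foods, `[[`, character(1),
                                 "food_guide_category"),
    commercial_count = unname(cls$weights),
    as.data.frame(cls$approved),
    n_models_approving = unname(mc$counts),
    check.names = FALSE, stringsAsFactors = FALSE)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    seed <- config$seed
    write_report_csv(atab, file.path(config$out_dir,
                                     "approval_summary.csv"), seed)
    write_report_csv(kappa_table(am),
                     file.path(config$out_dir, "kappa_matrix.csv"), seed)
    bd_out <- bd$table
    bd_out$pct_commercials_approved <-
      round_half_up(bd_out$pct_commercials_approved, 1)
    write_report_csv(bd_out, file.path(config$out_dir,
                                       "category_breakdown.csv"), seed)
    write_report_csv(per_food, file.path(config$out_dir, "per_food.csv"),
                     seed)
    write_report_csv(mc$distribution,
                     file.path(config$out_dir,
                               "approving_model_distribution.csv"), seed)
    writeLines(log_lines, file.path(config$out_dir, "run.log"))
    logf("stage=report out_dir=%s", config$out_dir)
  }

  invisible(structure(
    list(dataset = dataset, classifications = cls, summaries = summaries,
         approval_table = atab, kappa = am, breakdown = bd,
         model_counts = mc, models = models, per_food = per_food,
         log = log_lines),
    class = "pipeline_result"))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d foods, models: %s\n",
              length(x$dataset$foods), paste(x$models, collapse = ", ")))
  print(x$approval_table)
  invisible(x)
}
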
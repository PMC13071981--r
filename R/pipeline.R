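# End-to-end orchestration: simulate (or read) -> score -> subtype ->
# thresholds -> signature -> evaluate, with per-stage CSVs, a JSON report
# and a provenance block.  Every stage is a pure function of
# (config, seed, inputs); the report hash covers the statistics only, so
# identical config + seed reproduce it bit-for-bit.

#' Pipeline run configuration
#'
#' @param mode Input mode: `"synthetic"` (simulate a cohort),
#'   `"cell-tables"` (read a per-cell CSV plus a patient clinical CSV) or
#'   `"patient-table"` (read a patient-level CSV carrying scores).
#' @param seed Integer seed recorded in the report and driving all
#'   randomness.
#' @param n_patients Cohort size in synthetic mode.
#' @param cells_file,patients_file Input CSV paths for the file-based
#'   modes.
#' @param threshold_policy `"estimate"` (median/scan/selection) or
#'   `"fixed"` (published cutoffs, no estimation).
#' @param applicability `"cohort"` or `"restricted"`, see
#'   [signature_scores()].
#' @param missing Missing-component handling, `"zero"` or `"exclude"`.
#' @param horizons ROC follow-up horizons in months (`Inf` = any time).
#' @param covariates Covariate columns for the multivariate Cox model, in
#'   addition to the binary signature stratum.
#' @param output_dir Directory for stage CSVs and the JSON report; `NULL`
#'   keeps everything in memory.
#' @param resume Reuse stage CSVs already present in `output_dir` when the
#'   recorded config hash matches.
#' @param sim Extra arguments passed to [sim_config()] in synthetic mode.
#' @return A validated list of class `ihc_run_config`.
#' @export
run_config <- function(mode = c("synthetic", "cell-tables", "patient-table"),
                       seed = 1L, n_patients = 293,
                       cells_file = NULL, patients_file = NULL,
                       threshold_policy = c("estimate", "fixed"),
                       applicability = c("cohort", "restricted"),
                       missing = c("zero", "exclude"),
                       horizons = c(60, Inf),
                       covariates = c("grade", "subtype"),
                       output_dir = NULL, resume = FALSE, sim = list()) {
  mode <- match.arg(mode)
  threshold_policy <- match.arg(threshold_policy)
  applicability <- match.arg(applicability)
  missing <- match.arg(missing)
  if (mode == "cell-tables" &&
      (is.null(cells_file) || !file.exists(cells_file))) {
    abort("`cells_file` must exist in cell-tables mode.")
  }
  if (mode %in% c("cell-tables", "patient-table") &&
      (is.null(patients_file) || !file.exists(patients_file))) {
    abort("`patients_file` must exist in file-based modes.")
  }
  structure(list(
    mode = mode, seed = as.integer(seed), n_patients = n_patients,
    cells_file = cells_file, patients_file = patients_file,
    threshold_policy = threshold_policy, applicability = applicability,
    missing = missing, horizons = horizons, covariates = covariates,
    output_dir = output_dir, resume = isTRUE(resume), sim = sim),
    class = "ihc_run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [run_config()].
#' @return An `ihc_run_config` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  raw <- yaml::read_yaml(path)
  raw$horizons <- vapply(raw$horizons %||% c(60, Inf),
                         function(h) if (identical(h, "Inf")) Inf
                                     else as.numeric(h),
                         numeric(1))
  do.call(run_config, raw)
}

# Hash of the statistical content of a config (not of the output paths).
config_hash <- function(config) {
  core <- config[setdiff(names(config), c("output_dir", "resume"))]
  rlang::hash(core)
}

require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(miss, collapse = ", ")))
  }
  invisible(df)
}

stage_path <- function(config, name) {
  if (is.null(config$output_dir)) NULL
  else file.path(config$output_dir, paste0(name, ".csv"))
}

write_stage <- function(df, config, name) {
  path <- stage_path(config, name)
  if (!is.null(path)) readr::write_csv(df, path)
  df
}

# Resume from a cached stage CSV if the config hash on disk matches.
read_stage_if_cached <- function(config, name) {
  path <- stage_path(config, name)
  if (is.null(path) || !config$resume || !file.exists(path)) return(NULL)
  hash_file <- file.path(config$output_dir, "config_hash")
  if (!file.exists(hash_file) ||
      readLines(hash_file, n = 1) != config_hash(config)) return(NULL)
  readr::read_csv(path, show_col_types = FALSE)
}

#' Run the full signature pipeline
#'
#' Orchestrates the stages appropriate to the input mode: synthetic
#' simulation or file ingestion, cell-table scoring and aggregation,
#' subtype assignment, threshold estimation (or fixed published cutoffs),
#' signature composition, and survival/ROC evaluation.  Deterministic
#' given config + seed; the returned report carries a hash over all
#' computed statistics.
#'
#' @param config An [run_config()] object.
#' @return A list of class `ihc_report`: `config_hash`, `seed`, stage
#'   tables (`patients`, `thresholds`, `signature`), the evaluation
#'   statistics (`stats`), `report_hash`, and `provenance`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "ihc_run_config")) config <- do.call(run_config, config)
  if (!is.null(config$output_dir) &&
      !dir.exists(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE)
  }
  messages <- character()
  log_msg <- function(...) {
    messages <<- c(messages, sprintf(...))
  }

  # --- stage 1: obtain a patient-level table with biomarker scores -------
  patients <- read_stage_if_cached(config, "patients")
  if (is.null(patients)) {
    patients <- switch(
      config$mode,
      "synthetic" = {
        sim <- do.call(sim_config, modifyList(
          list(n_patients = config$n_patients, seed = config$seed),
          config$sim))
        simulate_cohort(sim)
      },
      "cell-tables" = {
        cells <- readr::read_csv(config$cells_file, show_col_types = FALSE)
        clinical <- readr::read_csv(config$patients_file,
                                    show_col_types = FALSE)
        core_scores <- score_cells(cells)
        n_fail <- sum(!core_scores$qc_pass) / length(BIOMARKERS)
        if (n_fail > 0) log_msg("%d core(s) failed QC", n_fail)
        wide <- scores_to_wide(aggregate_patient(core_scores))
        dplyr::left_join(clinical, wide, by = "patient_id")
      },
      "patient-table" = readr::read_csv(config$patients_file,
                                        show_col_types = FALSE))
    require_columns(patients, c("patient_id", "time", "event",
                                tolower(BIOMARKERS)),
                    "Patient table")
    # --- stage 2: molecular subtype -----------------------------------
    if (!"subtype" %in% names(patients)) {
      patients <- assign_subtypes(patients)
    }
    write_stage(patients, config, "patients")
  }

  # --- stage 3: thresholds ---------------------------------------------
  thresholds <- estimate_thresholds(patients,
                                    policy = config$threshold_policy)
  log_msg("threshold policy: %s", config$threshold_policy)
  write_stage(thresholds, config, "thresholds")

  # --- stage 4: signature ----------------------------------------------
  signature <- signature_scores(patients, thresholds,
                                applicability = config$applicability,
                                missing = config$missing)
  write_stage(signature, config, "signature")

  # --- stage 5: evaluation ---------------------------------------------
  kept <- dplyr::inner_join(
    signature[signature$included & !is.na(signature$score), ],
    patients[, c("patient_id", "time", "event", config$covariates)],
    by = "patient_id")
  stats <- evaluate_signature(kept, horizons = config$horizons,
                              covariates = config$covariates)
  stats$signature_distribution <- signature_distribution(signature)
  stats$threshold_summary <- thresholds[, c("biomarker", "subtype_group",
                                            "method", "cutoff", "logrank_p",
                                            "hr", "n_high", "n_low")]
  stats$subtype_counts <- dplyr::count(patients, .data$subtype)

  report_hash <- rlang::hash(stats)
  report <- structure(list(
    config_hash = config_hash(config), seed = config$seed,
    mode = config$mode, threshold_policy = config$threshold_policy,
    patients = patients, thresholds = thresholds, signature = signature,
    stats = stats, report_hash = report_hash, log = messages,
    provenance = list(
      package_version = as.character(utils::packageVersion("ihcsig")),
      r_version = paste(R.version$major, R.version$minor, sep = "."))),
    class = "ihc_report")

  if (!is.null(config$output_dir)) {
    writeLines(config_hash(config),
               file.path(config$output_dir, "config_hash"))
    jsonlite::write_json(
      report_to_json(report),
      file.path(config$output_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# Survival and classification statistics for the included patients.
evaluate_signature <- function(kept, horizons = c(60, Inf),
                               covariates = character()) {
  if (nrow(kept) < 4 || sum(kept$event) < 1) {
    abort("Too few included patients/events to evaluate the signature.")
  }
  st3 <- factor(kept$stratum3, levels = c("<0", "=0", ">0"))
  st2 <- factor(kept$stratum2, levels = c("<=0", ">0"))
  out <- list()
  out$n_included <- nrow(kept)
  out$n_strata3 <- as.list(table(st3))
  out$km_binary <- km_estimate(kept$time, kept$event, st2)
  out$km_three <- km_estimate(kept$time, kept$event, st3)
  lr2 <- suppressWarnings(
    logrank_test(kept$time, kept$event, st2, test_level = ">0"))
  out$logrank_binary <- lr2
  pos_vs_zero <- kept$stratum3 %in% c(">0", "=0")
  if (dplyr::n_distinct(kept$stratum3[pos_vs_zero]) == 2) {
    out$logrank_pos_vs_zero <- suppressWarnings(logrank_test(
      kept$time[pos_vs_zero], kept$event[pos_vs_zero],
      factor(kept$stratum3[pos_vs_zero], c("=0", ">0")), test_level = ">0"))
  }
  pos_vs_neg <- kept$stratum3 %in% c(">0", "<0")
  if (dplyr::n_distinct(kept$stratum3[pos_vs_neg]) == 2) {
    out$logrank_pos_vs_neg <- suppressWarnings(logrank_test(
      kept$time[pos_vs_neg], kept$event[pos_vs_neg],
      factor(kept$stratum3[pos_vs_neg], c("<0", ">0")), test_level = ">0"))
  }
  covs <- intersect(covariates, names(kept))
  design <- data.frame(signature_high = as.integer(kept$stratum2 == ">0"))
  for (cv in covs) {
    v <- kept[[cv]]
    if (dplyr::n_distinct(v[!is.na(v)]) > 1) design[[cv]] <- v
  }
  # sparse covariate levels (few patients or events) can push a dummy's
  # coefficient towards infinity; the diagnostics are kept in the report
  # instead of surfacing as warnings on every run
  out$cox_multivariate <- tryCatch({
    fit <- suppressWarnings(cox_fit(kept$time, kept$event, design))
    list(coefficients = tidy(fit), diagnostics = glance(fit))
  }, error = function(e) NULL)
  out$roc <- lapply(horizons, function(h) {
    tryCatch(glance(roc_at_horizon(kept$score, kept$time, kept$event,
                                   horizon = h, cutoff = 0)),
             error = function(e) NULL)
  })
  names(out$roc) <- paste0("horizon_", ifelse(is.infinite(horizons),
                                              "any", horizons))
  # 2x2: signature call vs relapse status (any time)
  tab <- table(factor(kept$score > 0, c(FALSE, TRUE),
                      c("<=0", ">0")),
               factor(kept$event == 1, c(FALSE, TRUE),
                      c("no_relapse", "relapse")))
  out$fisher <- fisher_2x2(tab)
  out$contingency <- as.data.frame(tab)
  out
}

# JSON-friendly view of a report (tibbles become data frame records).
report_to_json <- function(report) {
  list(seed = report$seed, mode = report$mode,
       threshold_policy = report$threshold_policy,
       config_hash = report$config_hash,
       report_hash = report$report_hash,
       provenance = report$provenance,
       stats = report$stats,
       log = report$log)
}

#' @export
print.ihc_report <- function(x, ...) {
  cat("ihcsig pipeline report (mode:", x$mode, ", seed:", x$seed, ")\n")
  cat("  patients:", nrow(x$patients),
      "| included in signature:", x$stats$n_included, "\n")
  lr <- x$stats$logrank_binary
  cat(sprintf("  binary stratum log-rank: HR = %.4f [%.4f, %.4f], p = %.3g\n",
              lr$hr, lr$hr_lower, lr$hr_upper, lr$p))
  for (nm in names(x$stats$roc)) {
    r <- x$stats$roc[[nm]]
    if (!is.null(r)) {
      cat(sprintf("  ROC %s: AUC = %.4f, sens = %.0f%%, spec = %.0f%%\n",
                  nm, r$auc, 100 * r$sensitivity, 100 * r$specificity))
    }
  }
  cat("  report hash:", x$report_hash, "\n")
  invisible(x)
}
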
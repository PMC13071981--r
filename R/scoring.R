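# Per-cell measurements -> per-core -> per-patient biomarker scores.
# Scoring always operates on tumour-class cells only; cores contribute only
# if they pass the minimum-tumour-cell QC rule.

CELL_COLUMNS <- c("patient_id", "core_id", "cell_class",
                  "od_nuclear", "od_cytoplasm", "od_perinuclear", "od_cell")

check_cells <- function(cells, require = CELL_COLUMNS) {
  miss <- setdiff(require, names(cells))
  if (length(miss)) {
    abort(paste0("Cell table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  od_cols <- grep("^od_", require, value = TRUE)
  for (col in od_cols) {
    if (any(cells[[col]] < 0, na.rm = TRUE)) {
      abort(paste0("Negative optical density in `", col, "`."))
    }
  }
  bad <- setdiff(unique(cells$cell_class), c("tumour", "stroma"))
  if (length(bad)) {
    abort(paste0("Unknown cell_class value(s): ", paste(bad, collapse = ", ")))
  }
  invisible(cells)
}

#' Bin a continuous optical density into an ordinal intensity
#'
#' The intensity of a cell is the number of thresholds at or below its
#' optical density (right-open bins): density below the first threshold is
#' intensity 0, at or above the last is the maximum intensity.  Monotone
#' non-decreasing in density.
#'
#' @param density Numeric vector of DAB optical densities, >= 0.
#' @param od_bins Strictly ascending thresholds; length = maximum intensity.
#' @return Integer vector of intensities in `0..length(od_bins)`.
#' @export
#' @examples
#' bin_intensity(c(0, 0.45, 2), default_od_bins())
bin_intensity <- function(density, od_bins = default_od_bins()) {
  if (any(density < 0, na.rm = TRUE)) abort("Optical density must be >= 0.")
  if (any(diff(od_bins) <= 0)) abort("`od_bins` must be strictly ascending.")
  findInterval(density, od_bins)
}

#' Core-level quality control
#'
#' A core is analysable only if it contains at least `min_tumour_cells`
#' tumour-class cells (default 100); smaller cores are excluded from
#' scoring.
#'
#' @param cells Cell records from a single core.
#' @param min_tumour_cells QC floor on the tumour cell count.
#' @return `TRUE` if the core passes.
#' @export
qc_core <- function(cells, min_tumour_cells = 100L) {
  check_cells(cells, require = c("core_id", "cell_class"))
  if (dplyr::n_distinct(cells$core_id) > 1) {
    abort("`qc_core()` expects cells from a single core.")
  }
  sum(cells$cell_class == "tumour") >= min_tumour_cells
}

# Intensities of the tumour cells of one core at a spec's localisation.
tumour_intensities <- function(cells, spec) {
  col <- od_column(spec$localisation)
  check_cells(cells, require = c("cell_class", col))
  tum <- cells[cells$cell_class == "tumour", ]
  if (nrow(tum) == 0) {
    abort("No tumour-class cells: score is undefined for an empty core.")
  }
  bin_intensity(tum[[col]], spec$od_bins[[1]])
}

#' Percent of tumour cells positive for a biomarker
#'
#' The percentage of tumour-class cells whose intensity at the biomarker's
#' localisation is at least 1.  Stromal cells never contribute.
#'
#' @param cells Cell records of one core.
#' @param spec A one-row slice of [biomarker_specs()].
#' @return Percentage in \[0, 100\].
#' @export
percent_positive <- function(cells, spec = biomarker_specs()[1, ]) {
  k <- tumour_intensities(cells, spec)
  100 * mean(k >= 1)
}

#' Histochemical score (H-score) of a core
#'
#' `H = sum_k k * (% tumour cells with intensity k)` for `k = 1..max`,
#' giving a range of 0-300 on the 0-3 intensity scale and 0-400 on the 0-4
#' scale.  Equals [percent_positive()] when every positive cell has
#' intensity 1, and `100 * max_intensity` when all cells stain maximally.
#'
#' @inheritParams percent_positive
#' @return H-score in \[0, 100 * max_intensity\].
#' @export
h_score <- function(cells, spec = biomarker_specs()[2, ]) {
  k <- tumour_intensities(cells, spec)
  sum(k) / length(k) * 100
}

#' Score a cell table into per-core biomarker scores
#'
#' Applies QC and the per-biomarker scoring rules to every (patient, core)
#' group of a digital-pathology cell table.  Cores failing QC are kept in
#' the output with `qc_pass = FALSE` and `NA` scores.
#'
#' @param cells Cell table (see [simulate_cells()] for the schema); column
#'   names can be adapted with `col_map`, a named character vector mapping
#'   canonical names to the table's names, e.g.
#'   `c(od_cell = "Cell.DAB.OD.mean")`.
#' @param specs Biomarker specifications, [biomarker_specs()].
#' @param min_tumour_cells QC floor on tumour cells per core.
#' @param col_map Optional column renaming, canonical = actual.
#' @return A tibble with one row per core x biomarker: `patient_id`,
#'   `core_id`, `biomarker`, `method`, `n_tumour_cells`, `qc_pass`,
#'   `percent_positive`, `h_score`, `value` (the score selected by the
#'   biomarker's method).
#' @export
score_cells <- function(cells, specs = biomarker_specs(),
                        min_tumour_cells = 100L, col_map = NULL) {
  if (!is.null(col_map)) {
    idx <- match(unname(col_map), names(cells))
    if (anyNA(idx)) abort("`col_map` names columns absent from the table.")
    names(cells)[idx] <- names(col_map)
  }
  check_cells(cells)
  cores <- dplyr::group_split(dplyr::group_by(cells, .data$patient_id,
                                              .data$core_id))
  purrr::map_dfr(cores, function(core) {
    n_tum <- sum(core$cell_class == "tumour")
    pass <- n_tum >= min_tumour_cells
    purrr::map_dfr(seq_len(nrow(specs)), function(i) {
      spec <- specs[i, ]
      pp <- hs <- NA_real_
      if (pass) {
        k <- tumour_intensities(core, spec)
        pp <- 100 * mean(k >= 1)
        if (spec$method == "h_score") hs <- sum(k) / length(k) * 100
      }
      tibble::tibble(
        patient_id = core$patient_id[1], core_id = core$core_id[1],
        biomarker = spec$biomarker, method = spec$method,
        n_tumour_cells = n_tum, qc_pass = pass,
        percent_positive = pp, h_score = hs,
        value = if (spec$method == "h_score") hs else pp)
    })
  })
}

#' Aggregate triplicate core scores to patient level
#'
#' Patients are represented by multiple (typically three) cores; the
#' patient-level biomarker score is the mean (or median) of the QC-passing
#' cores' scores, and is missing when no core passes.
#'
#' @param core_scores Output of [score_cells()].
#' @param agg `"mean"` (default) or `"median"`.
#' @return A tibble with one row per patient x biomarker: `patient_id`,
#'   `biomarker`, `value`, `n_cores`, `n_cores_pass`.
#' @export
aggregate_patient <- function(core_scores, agg = c("mean", "median")) {
  agg <- match.arg(agg)
  fun <- if (agg == "mean") mean else stats::median
  need <- c("patient_id", "biomarker", "qc_pass", "value")
  miss <- setdiff(need, names(core_scores))
  if (length(miss)) {
    abort(paste0("Core-score table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  core_scores |>
    dplyr::group_by(.data$patient_id, .data$biomarker) |>
    dplyr::summarise(
      n_cores = dplyr::n(),
      n_cores_pass = sum(.data$qc_pass),
      value = if (any(.data$qc_pass)) fun(.data$value[.data$qc_pass])
              else NA_real_,
      .groups = "drop") |>
    dplyr::relocate("value", .after = "biomarker")
}

#' Pivot patient-level biomarker scores to one column per readout
#'
#' @param patient_scores Output of [aggregate_patient()].
#' @return A tibble with `patient_id` and one lower-cased column per
#'   biomarker readout.
#' @export
scores_to_wide <- function(patient_scores) {
  patient_scores |>
    dplyr::mutate(biomarker = tolower(.data$biomarker)) |>
    tidyr::pivot_wider(id_cols = "patient_id", names_from = "biomarker",
                       values_from = "value")
}
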
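# Biomarker scoring specifications and shipped defaults: localisation,
# scoring method, intensity scale, optical-density bins, published cutoffs
# and the subtype sets where each biomarker carries prognostic signal.

#' Default optical-density intensity bins
#'
#' Digital-pathology exports carry continuous DAB optical densities; scoring
#' needs an ordinal 0..max intensity.  The thresholds separating the classes
#' are a platform calibration, not a published constant, so the shipped
#' defaults are an even grid (0.2, 0.4, 0.6, and 0.8 for a 0-4 scale) and
#' every scoring function accepts overrides.
#'
#' @param max_intensity Top intensity class, 3 or 4.
#' @return Numeric vector of `max_intensity` strictly ascending thresholds.
#' @export
default_od_bins <- function(max_intensity = 3) {
  if (!max_intensity %in% c(3, 4)) {
    abort("`max_intensity` must be 3 or 4.")
  }
  c(0.2, 0.4, 0.6, 0.8)[seq_len(max_intensity)]
}

#' Biomarker scoring specifications
#'
#' One row per biomarker readout: which subcellular compartment is scored,
#' whether the readout is a percent-positivity or an H-score, the intensity
#' scale, and the optical-density bin thresholds.  TOP2A and perinuclear
#' p-mTOR stain homogeneously and are scored as percent positive; PTEN,
#' EGFR, IGF1R and whole-cell p-mTOR stain heterogeneously and are scored
#' with an H-score.  All readouts default to the 0-3 intensity scale; pass
#' `max_intensity` overrides per biomarker for a 0-4 scale.
#'
#' @param max_intensity Named integer vector of per-biomarker overrides,
#'   e.g. `c(EGFR = 4)`.
#' @param od_bins Named list of per-biomarker optical-density threshold
#'   overrides; each entry a strictly ascending numeric vector whose length
#'   equals that biomarker's `max_intensity`.
#' @return A tibble with columns `biomarker`, `localisation`, `method`,
#'   `max_intensity` and list-column `od_bins`.
#' @export
biomarker_specs <- function(max_intensity = NULL, od_bins = NULL) {
  specs <- tibble::tibble(
    biomarker     = BIOMARKERS,
    localisation  = c("nuclear", "nuclear", "wholecell", "wholecell",
                      "wholecell", "perinuclear"),
    method        = c("percent_positive", "h_score", "h_score", "h_score",
                      "h_score", "percent_positive"),
    max_intensity = 3L
  )
  if (!is.null(max_intensity)) {
    bad <- setdiff(names(max_intensity), specs$biomarker)
    if (length(bad)) abort(paste0("Unknown biomarker(s): ",
                                  paste(bad, collapse = ", ")))
    idx <- match(names(max_intensity), specs$biomarker)
    specs$max_intensity[idx] <- as.integer(max_intensity)
  }
  if (!all(specs$max_intensity %in% c(3L, 4L))) {
    abort("Intensity scales other than 0-3 and 0-4 are not supported.")
  }
  specs$od_bins <- lapply(specs$max_intensity, default_od_bins)
  if (!is.null(od_bins)) {
    bad <- setdiff(names(od_bins), specs$biomarker)
    if (length(bad)) abort(paste0("Unknown biomarker(s): ",
                                  paste(bad, collapse = ", ")))
    for (nm in names(od_bins)) {
      i <- match(nm, specs$biomarker)
      bins <- od_bins[[nm]]
      if (length(bins) != specs$max_intensity[i] ||
          any(diff(bins) <= 0) || any(bins < 0)) {
        abort(paste0("`od_bins` for ", nm, " must be ",
                     specs$max_intensity[i],
                     " strictly ascending non-negative thresholds."))
      }
      specs$od_bins[[i]] <- bins
    }
  }
  specs
}

# Maps a localisation to the optical-density column of the cell table.
od_column <- function(localisation) {
  switch(localisation,
         nuclear     = "od_nuclear",
         wholecell   = "od_cell",
         perinuclear = "od_perinuclear",
         abort(paste0("Unknown localisation: ", localisation)))
}

#' Subtype groups in which each biomarker carries prognostic signal
#'
#' The published per-biomarker survival associations hold in specific
#' subtype groups only: TOP2A in ER-negative disease (HER2-enriched and
#' TNBC), PTEN in HER2-positive plus Luminal B HER2-negative, EGFR in
#' everything except Luminal A, IGF1R in Luminal B HER2-negative, whole-cell
#' p-mTOR in Luminal B, and perinuclear p-mTOR in HER2-positive disease.
#' No biomarker captures Luminal A.
#'
#' @return A tibble with columns `biomarker` and list-column `subtypes`.
#' @export
applicable_subtypes <- function() {
  tibble::tibble(
    biomarker = BIOMARKERS,
    subtypes = list(
      c("HER2_enriched", "TNBC"),
      c("LuminalB_HER2neg", "LuminalB_HER2pos", "HER2_enriched"),
      c("LuminalB_HER2neg", "LuminalB_HER2pos", "HER2_enriched", "TNBC"),
      "LuminalB_HER2neg",
      c("LuminalB_HER2neg", "LuminalB_HER2pos"),
      c("LuminalB_HER2pos", "HER2_enriched")
    )
  )
}

#' Published high/low dichotomisation thresholds
#'
#' The fixed cutoffs reported for each biomarker readout within its
#' applicable subtype group: TOP2A 45 (percent positive, ER-negative), PTEN
#' 100 (H-score median, HER2-positive and Luminal B HER2-negative), IGF1R
#' 219 (H-score median, Luminal B HER2-negative), whole-cell p-mTOR 100
#' (H-score, Luminal B), perinuclear p-mTOR 1 (percent positive,
#' HER2-positive).  EGFR has no numeric published cutoff ("extremely strong
#' staining"); this package operationalises it as the `egfr_quantile`
#' quantile (default 0.95) of the non-Luminal-A cohort, computed from the
#' data at hand, so its `cutoff` here is `NA` with `rule = "quantile"`.
#'
#' @param egfr_quantile Quantile of the non-Luminal-A EGFR distribution used
#'   as the "extremely strong staining" cutoff.
#' @return A tibble with one row per biomarker: `biomarker`, `cutoff`,
#'   `rule` (`"fixed"` or `"quantile"`), `quantile`, and list-column
#'   `subtype_group` (the subtypes pooled when the cutoff was derived).
#' @export
default_thresholds <- function(egfr_quantile = 0.95) {
  stopifnot(egfr_quantile > 0, egfr_quantile < 1)
  tbl <- tibble::tibble(
    biomarker = BIOMARKERS,
    cutoff    = c(45, 100, NA_real_, 219, 100, 1),
    rule      = c("fixed", "fixed", "quantile", "fixed", "fixed", "fixed"),
    quantile  = c(NA, NA, egfr_quantile, NA, NA, NA)
  )
  tbl$subtype_group <- applicable_subtypes()$subtypes
  tbl
}

#' Default hazard-ratio effect sizes for the synthetic cohort
#'
#' Per-biomarker relapse hazard ratios applied to biomarker-high patients in
#' the simulator, taken from the published univariate associations: TOP2A
#' 0.287, PTEN 0.356, IGF1R 0.2816, whole-cell p-mTOR 0.3832, perinuclear
#' p-mTOR 0.2977.  EGFR showed no significant association and defaults to a
#' null effect (hazard ratio 1).
#'
#' @return Named numeric vector over [biomarker_names()].
#' @export
default_effect_hrs <- function() {
  c(TOP2A = 0.287, PTEN = 0.356, EGFR = 1,
    IGF1R = 0.2816, pmTOR_wholecell = 0.3832, pmTOR_perinuclear = 0.2977)
}
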
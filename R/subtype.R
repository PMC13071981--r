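# St Gallen molecular subtype assignment from ER/PR/HER2/Ki67 readouts.

#' Allred proportion and total score
#'
#' The Allred proportion score bins the percentage of positive nuclei
#' (0: none; 1: < 1%; 2: 1-10%; 3: > 10% to one third; 4: over one third to
#' two thirds; 5: over two thirds), and the total score adds the dominant
#' intensity (0-3).  A receptor is called positive when the proportion
#' score is at least 2 and the total at least 3 -- equivalently, when at
#' least 1% of cells show nuclear staining of any intensity.
#'
#' @param percent Percent of positive nuclei, in \[0, 100\].
#' @param intensity Dominant staining intensity, integer 0-3.
#' @return A tibble with columns `proportion`, `intensity`, `total` and
#'   `positive`.
#' @export
#' @examples
#' allred_total(5, 1)    # proportion 2, total 3: positive
#' allred_total(0.5, 3)  # proportion 1: negative
allred_total <- function(percent, intensity) {
  if (any(percent < 0 | percent > 100, na.rm = TRUE)) {
    abort("`percent` must lie in [0, 100].")
  }
  if (any(!intensity %in% c(0:3, NA))) {
    abort("`intensity` must be an integer in 0..3.")
  }
  proportion <- allred_proportion(percent)
  total <- proportion + intensity
  tibble::tibble(
    proportion = proportion,
    intensity = as.integer(intensity),
    total = as.integer(total),
    positive = proportion >= 2L & total >= 3L)
}

allred_proportion <- function(percent) {
  dplyr::case_when(
    is.na(percent) ~ NA_integer_,
    percent == 0 ~ 0L,
    percent < 1 ~ 1L,
    percent <= 10 ~ 2L,
    percent <= 100 / 3 ~ 3L,
    percent <= 200 / 3 ~ 4L,
    TRUE ~ 5L)
}

#' Ki67 positivity
#'
#' Ki67 is positive when the proportion of stained nuclei is strictly
#' greater than 14%; exactly 14% is negative.
#'
#' @param ki67_percent Percent of Ki67-positive nuclei.
#' @return Logical vector.
#' @export
ki67_positive <- function(ki67_percent) {
  if (any(ki67_percent < 0 | ki67_percent > 100, na.rm = TRUE)) {
    abort("`ki67_percent` must lie in [0, 100].")
  }
  ki67_percent > 14
}

#' Assign St Gallen molecular subtypes
#'
#' Adds receptor status and subtype columns to a patient table carrying
#' `er_percent`, `er_intensity`, `pr_percent`, `pr_intensity`,
#' `her2_positive` and `ki67_percent`.  The five rules partition every
#' complete marker set:
#' \itemize{
#'   \item Luminal A: ER+ and/or PR+, HER2-, Ki67-
#'   \item Luminal B HER2-: ER+ and/or PR+, HER2-, Ki67+
#'   \item Luminal B HER2+: ER+ and/or PR+, HER2+
#'   \item HER2-enriched: ER-, PR-, HER2+
#'   \item TNBC: ER-, PR-, HER2-
#' }
#' Patients with any missing marker get subtype `"Unknown"`; they are kept
#' in the table but excluded from subtype-specific analyses downstream.
#'
#' @param patients Patient tibble with the six marker columns.
#' @return The input with `er_status`, `pr_status`, `ki67_status` (logical)
#'   and `subtype` (character) columns added or replaced.
#' @export
assign_subtypes <- function(patients) {
  need <- c("er_percent", "er_intensity", "pr_percent", "pr_intensity",
            "her2_positive", "ki67_percent")
  miss <- setdiff(need, names(patients))
  if (length(miss)) {
    abort(paste0("Patient table is missing marker column(s): ",
                 paste(miss, collapse = ", ")))
  }
  er <- allred_total(patients$er_percent, patients$er_intensity)$positive
  pr <- allred_total(patients$pr_percent, patients$pr_intensity)$positive
  ki67 <- ki67_positive(patients$ki67_percent)
  her2 <- patients$her2_positive
  patients$er_status <- er
  patients$pr_status <- pr
  patients$ki67_status <- ki67
  patients$subtype <- dplyr::case_when(
    is.na(er) | is.na(pr) | is.na(her2) ~ "Unknown",
    (er | pr) & !her2 & is.na(ki67) ~ "Unknown",
    (er | pr) & her2 ~ "LuminalB_HER2pos",
    (er | pr) & !her2 & !ki67 ~ "LuminalA",
    (er | pr) & !her2 & ki67 ~ "LuminalB_HER2neg",
    !er & !pr & her2 ~ "HER2_enriched",
    TRUE ~ "TNBC")
  patients
}
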
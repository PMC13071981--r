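# The composite signature: six per-biomarker high/low calls mapped to
# {+1, -1} (0 for missing), summed into a score in [-6, +6], and
# stratified.  Luminal A and unknown-subtype patients are excluded from
# stratified analyses because no biomarker captures Luminal A.

#' Component score of one biomarker readout
#'
#' +1 when the score is non-missing and at or above the cutoff, -1 when
#' non-missing and below, 0 when missing.  In restricted-applicability mode
#' a readout also contributes 0 for patients whose subtype is outside the
#' biomarker's applicable set.
#'
#' @param value Numeric score vector (NA = missing).
#' @param cutoff High/low boundary; high is `value >= cutoff`.
#' @param subtype Optional per-patient subtype vector, required when
#'   `applicable` is given.
#' @param applicable Optional character vector of subtypes in which the
#'   biomarker applies; patients outside it score 0.
#' @return Integer vector in \{-1, 0, +1\}.
#' @export
#' @examples
#' component_score(c(50, 44.9, NA), cutoff = 45)
component_score <- function(value, cutoff, subtype = NULL,
                            applicable = NULL) {
  if (is.na(cutoff)) abort("`cutoff` must be defined for the biomarker.")
  out <- ifelse(is.na(value), 0L, ifelse(value >= cutoff, 1L, -1L))
  if (!is.null(applicable)) {
    if (is.null(subtype)) {
      abort("`subtype` is required when `applicable` is given.")
    }
    out[!subtype %in% applicable] <- 0L
  }
  out
}

#' Stratify a composite signature score
#'
#' Three-group stratification (`">0"`, `"=0"`, `"<0"`) and the binary
#' collapse (`">0"` versus `"<=0"`).
#'
#' @param score Integer signature scores.
#' @return A tibble with `stratum3` and `stratum2` character columns.
#' @export
stratify <- function(score) {
  tibble::tibble(
    stratum3 = dplyr::case_when(is.na(score) ~ NA_character_,
                                score > 0 ~ ">0",
                                score == 0 ~ "=0",
                                TRUE ~ "<0"),
    stratum2 = dplyr::case_when(is.na(score) ~ NA_character_,
                                score > 0 ~ ">0",
                                TRUE ~ "<=0"))
}

#' Compose the six-component signature score
#'
#' Maps each of the six biomarker readouts to a \{-1, 0, +1\} component
#' against its threshold, sums them into the composite score (possible
#' range -6 to +6) and stratifies.  Missing readouts contribute 0 by
#' default -- the only reading under which odd composite scores can arise
#' from six plus/minus-one terms -- or, with `missing = "exclude"`,
#' patients with any missing component get an `NA` score.  Luminal A and
#' unknown-subtype patients are marked `included = FALSE` and carry no
#' strata.
#'
#' @param patients Patient tibble with `patient_id`, `subtype` and one
#'   lower-cased score column per biomarker readout.
#' @param thresholds Threshold table with `biomarker` and `cutoff` columns
#'   (e.g. from [estimate_thresholds()]); every biomarker needs a defined
#'   cutoff.
#' @param applicability `"cohort"` (default): every biomarker is scored
#'   cohort-wide with its threshold; `"restricted"`: a biomarker
#'   contributes 0 outside its applicable subtype set
#'   ([applicable_subtypes()]).
#' @param missing `"zero"` (default) or `"exclude"`.
#' @return A tibble, one row per patient: `patient_id`, `subtype`, six
#'   `comp_*` columns, `score`, `stratum3`, `stratum2`, `included`.
#' @export
signature_scores <- function(patients, thresholds,
                             applicability = c("cohort", "restricted"),
                             missing = c("zero", "exclude")) {
  applicability <- match.arg(applicability)
  missing <- match.arg(missing)
  need <- c("patient_id", "subtype", tolower(BIOMARKERS))
  miss <- setdiff(need, names(patients))
  if (length(miss)) {
    abort(paste0("Patient table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (!all(BIOMARKERS %in% thresholds$biomarker)) {
    abort("`thresholds` must cover all six biomarker readouts.")
  }
  applic <- applicable_subtypes()
  comps <- lapply(BIOMARKERS, function(bm) {
    cutoff <- thresholds$cutoff[match(bm, thresholds$biomarker)]
    if (is.na(cutoff)) {
      abort(paste0("No defined cutoff for ", bm, "."))
    }
    appl <- if (applicability == "restricted") {
      applic$subtypes[[match(bm, applic$biomarker)]]
    } else NULL
    component_score(patients[[tolower(bm)]], cutoff,
                    subtype = patients$subtype, applicable = appl)
  })
  names(comps) <- paste0("comp_", tolower(BIOMARKERS))
  comp_tbl <- tibble::as_tibble(comps)
  score <- as.integer(rowSums(comp_tbl))
  if (missing == "exclude") {
    any_missing <- Reduce(`|`, lapply(tolower(BIOMARKERS),
                                      function(b) is.na(patients[[b]])))
    score[any_missing] <- NA_integer_
  }
  included <- !patients$subtype %in% c("LuminalA", "Unknown") &
    !is.na(patients$subtype)
  strata <- stratify(score)
  strata[!included | is.na(score), ] <- NA_character_
  out <- dplyr::bind_cols(
    tibble::tibble(patient_id = patients$patient_id,
                   subtype = patients$subtype),
    comp_tbl,
    tibble::tibble(score = score, included = included),
    strata)
  class(out) <- c("ihc_signature", class(out))
  out
}

#' Frequency distribution of signature scores among included patients
#'
#' @param signature A [signature_scores()] result.
#' @return A tibble: `score`, `n`, `fraction` over included patients with a
#'   defined score.
#' @export
signature_distribution <- function(signature) {
  kept <- signature[signature$included & !is.na(signature$score), ]
  kept |>
    dplyr::count(.data$score, name = "n") |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::arrange(.data$score)
}
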
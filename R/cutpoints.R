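# Dichotomisation of continuous biomarker scores into high/low within a
# subtype group: median split, survival-optimised cutoff scanning, and the
# selection policy arbitrating between them.  "High" is score >= cutoff.

#' Median cutoff
#'
#' Sample median of the non-missing scores; patients at or above it are
#' "high".  A constant score vector is degenerate (everyone high).
#'
#' @param scores Numeric scores, missing values ignored.
#' @return The median, with attribute `degenerate` set when all non-missing
#'   scores are equal.
#' @export
median_cutoff <- function(scores) {
  scores <- scores[!is.na(scores)]
  if (length(scores) < 2) abort("Need at least two non-missing scores.")
  m <- median(scores)
  attr(m, "degenerate") <- length(unique(scores)) == 1
  m
}

#' Evaluate one high/low cutoff against survival
#'
#' Splits patients at `score >= cutoff` and runs the Mantel-Cox log-rank
#' test of high versus low, returning a one-row threshold result.
#'
#' @param scores,times,events Aligned per-patient vectors.
#' @param cutoff High/low boundary (high is `>= cutoff`).
#' @param biomarker,subtype_group,method Metadata stamped on the result.
#' @return A one-row tibble of class `ihc_threshold`: `biomarker`,
#'   `subtype_group`, `method`, `cutoff`, `n_high`, `n_low`, `logrank_p`,
#'   `hr`, `hr_lower`, `hr_upper`, `degenerate`, `note`.
#' @export
evaluate_cutoff <- function(scores, times, events, cutoff,
                            biomarker = NA_character_,
                            subtype_group = NA_character_,
                            method = "fixed") {
  keep <- !is.na(scores) & !is.na(times) & !is.na(events)
  scores <- scores[keep]; times <- times[keep]; events <- events[keep]
  high <- scores >= cutoff
  res <- tibble::tibble(
    biomarker = biomarker, subtype_group = subtype_group, method = method,
    cutoff = as.numeric(cutoff), n_high = sum(high), n_low = sum(!high),
    logrank_p = NA_real_, hr = NA_real_, hr_lower = NA_real_,
    hr_upper = NA_real_, degenerate = FALSE, note = NA_character_)
  if (!any(high) || all(high)) {
    res$degenerate <- TRUE
    res$note <- "all patients on one side of the cutoff"
  } else {
    lr <- suppressWarnings(logrank_test(
      times, events, factor(high, c(FALSE, TRUE), c("low", "high")),
      test_level = "high"))
    res$logrank_p <- lr$p; res$hr <- lr$hr
    res$hr_lower <- lr$hr_lower; res$hr_upper <- lr$hr_upper
    res$degenerate <- lr$degenerate
    if (lr$degenerate) res$note <- "a group has zero events"
  }
  class(res) <- c("ihc_threshold", class(res))
  res
}

#' Survival-optimised cutoff scan
#'
#' Evaluates every midpoint between consecutive distinct score values as a
#' candidate high/low cutoff, skipping candidates that would leave either
#' group below `min_group_frac` of the analysed patients, and picks the
#' candidate with the smallest log-rank p value (ties broken towards the
#' cutoff closest to the median score).  The minimal p value is optimistic:
#' it is the minimum over many correlated tests and overstates significance
#' unless corrected; an optional `adjust` applies [stats::p.adjust()]
#' across candidates for reporting (`p_adjusted`), but selection always
#' uses the raw minimum, matching the behaviour of cutoff-scanning tools
#' used in the field.
#'
#' @param scores,times,events Aligned per-patient vectors; missing scores
#'   are dropped.
#' @param min_group_frac Minimum fraction of patients in each arm.
#' @param adjust Optional multiplicity adjustment for the reported
#'   candidate p values (`"none"` default).
#' @param biomarker,subtype_group Metadata stamped on the results.
#' @return An object of class `ihc_cutscan`: a tibble of candidate
#'   threshold results with attribute `optimum` (the selected one-row
#'   result, `method = "scan"`).
#' @export
scan_cutoffs <- function(scores, times, events, min_group_frac = 0.1,
                         adjust = "none", biomarker = NA_character_,
                         subtype_group = NA_character_) {
  keep <- !is.na(scores) & !is.na(times) & !is.na(events)
  scores <- scores[keep]; times <- times[keep]; events <- events[keep]
  n <- length(scores)
  if (n < 10) abort("Cutoff scanning needs at least 10 patients.")
  if (min_group_frac < 0 || min_group_frac >= 0.5) {
    abort("`min_group_frac` must lie in [0, 0.5).")
  }
  uniq <- sort(unique(scores))
  if (length(uniq) < 2) abort("All scores are equal; nothing to scan.")
  cand <- (head(uniq, -1) + uniq[-1]) / 2
  min_n <- ceiling(min_group_frac * n)
  admissible <- vapply(cand, function(cc) {
    nh <- sum(scores >= cc)
    nh >= min_n && (n - nh) >= min_n
  }, logical(1))
  if (!any(admissible)) {
    abort("No admissible candidate cutoff under `min_group_frac`.")
  }
  cand <- cand[admissible]
  results <- purrr::map_dfr(cand, function(cc) {
    evaluate_cutoff(scores, times, events, cc, biomarker = biomarker,
                    subtype_group = subtype_group, method = "scan")
  })
  results$p_adjusted <- stats::p.adjust(results$logrank_p, method = adjust)
  med <- median(scores)
  ok <- which(!is.na(results$logrank_p))
  if (!length(ok)) abort("No candidate produced a valid log-rank test.")
  best_p <- min(results$logrank_p[ok])
  tied <- ok[results$logrank_p[ok] == best_p]
  opt_idx <- tied[which.min(abs(results$cutoff[tied] - med))]
  optimum <- results[opt_idx, ]
  class(optimum) <- c("ihc_threshold", setdiff(class(optimum), "ihc_cutscan"))
  structure(results, optimum = optimum,
            class = c("ihc_cutscan", class(results)))
}

#' Selected optimum of a cutoff scan
#' @param scan An [scan_cutoffs()] result.
#' @return The one-row optimum threshold result.
#' @export
scan_optimum <- function(scan) {
  if (!inherits(scan, "ihc_cutscan")) abort("Not an `ihc_cutscan` object.")
  attr(scan, "optimum")
}

#' @export
glance.ihc_cutscan <- function(x, ...) {
  opt <- attr(x, "optimum")
  opt$n_candidates <- nrow(x)
  opt
}

#' Arbitrate between the median split and the scanned optimum
#'
#' The median split is preferred as the unbiased choice: it is selected
#' whenever its log-rank p value is below `alpha`.  Otherwise the scanned
#' optimum is selected if it is *notably different* from the median split
#' -- its cutoff differs by more than `value_margin` (relative to the score
#' spread between the two cutoffs' range... measured as a fraction of the
#' observed score range) and its p value falls below `alpha`.  If neither
#' split is informative the median result is returned flagged
#' non-informative.
#'
#' @param median_result,scan_result One-row threshold results for the same
#'   biomarker and group ([evaluate_cutoff()] at the median, and
#'   [scan_optimum()] of a scan).
#' @param alpha Significance level of the policy.
#' @param value_margin Minimum relative cutoff difference (fraction of the
#'   larger cutoff magnitude) for the scan to count as "notably different".
#' @param score_range Optional observed score range used to scale the
#'   cutoff difference; defaults to the larger cutoff.
#' @return A one-row `ihc_threshold` with `selected` (`"median"` or
#'   `"scan"`) and a human-readable `rationale` column.
#' @export
select_threshold <- function(median_result, scan_result, alpha = 0.05,
                             value_margin = 0.2, score_range = NULL) {
  stopifnot(nrow(median_result) == 1, nrow(scan_result) == 1)
  scale <- score_range %||% max(abs(median_result$cutoff),
                                abs(scan_result$cutoff), 1e-12)
  rel_diff <- abs(scan_result$cutoff - median_result$cutoff) / scale
  med_sig <- !is.na(median_result$logrank_p) && median_result$logrank_p < alpha
  scan_sig <- !is.na(scan_result$logrank_p) && scan_result$logrank_p < alpha
  if (med_sig) {
    out <- median_result
    out$selected <- "median"
    out$rationale <- sprintf(
      "median split significant (p = %.3g < %.2g); unbiased choice kept",
      median_result$logrank_p, alpha)
  } else if (scan_sig && rel_diff > value_margin) {
    out <- scan_result
    out$selected <- "scan"
    out$rationale <- sprintf(
      paste0("median split not significant (p = %.3g); scanned cutoff ",
             "differs by %.0f%% of the score scale and is significant ",
             "(p = %.3g)"),
      median_result$logrank_p, 100 * rel_diff, scan_result$logrank_p)
  } else {
    out <- median_result
    out$selected <- "median"
    out$note <- "non-informative"
    out$rationale <- sprintf(
      paste0("neither split significant at %.2g (median p = %.3g, scan ",
             "p = %.3g); median kept, flagged non-informative"),
      alpha, median_result$logrank_p, scan_result$logrank_p)
  }
  class(out) <- unique(c("ihc_threshold", class(out)))
  out
}

#' Estimate high/low thresholds for every biomarker in its subtype group
#'
#' Applies the full threshold workflow per biomarker within the published
#' subtype group: median split, cutoff scan, and the [select_threshold()]
#' policy -- or, with `policy = "fixed"`, evaluates the published cutoffs
#' of [default_thresholds()] without estimation (the EGFR quantile rule is
#' still resolved from the data).
#'
#' @param patients Patient tibble with `subtype`, `time`, `event` and one
#'   lower-cased score column per biomarker.
#' @param policy `"estimate"` or `"fixed"`.
#' @param thresholds Fixed-threshold table, see [default_thresholds()].
#' @param min_group_frac,alpha,value_margin Passed to the scan/selection.
#' @return A tibble of one-row threshold results (class `ihc_threshold`),
#'   one per biomarker, with `subtype_group` collapsed to a `+`-separated
#'   label.
#' @export
estimate_thresholds <- function(patients,
                                policy = c("estimate", "fixed"),
                                thresholds = default_thresholds(),
                                min_group_frac = 0.1, alpha = 0.05,
                                value_margin = 0.2) {
  policy <- match.arg(policy)
  need <- c("subtype", "time", "event", tolower(thresholds$biomarker))
  miss <- setdiff(need, names(patients))
  if (length(miss)) {
    abort(paste0("Patient table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  purrr::map_dfr(seq_len(nrow(thresholds)), function(i) {
    row <- thresholds[i, ]
    grp <- row$subtype_group[[1]]
    lab <- paste(grp, collapse = "+")
    sub <- patients[patients$subtype %in% grp, ]
    sc <- sub[[tolower(row$biomarker)]]
    cutoff <- row$cutoff
    if (identical(row$rule, "quantile")) {
      pool <- patients[patients$subtype %in% setdiff(SUBTYPES, "LuminalA"), ]
      cutoff <- quantile(pool[[tolower(row$biomarker)]], row$quantile,
                         na.rm = TRUE, names = FALSE)
    }
    if (policy == "fixed") {
      out <- evaluate_cutoff(sc, sub$time, sub$event, cutoff,
                             biomarker = row$biomarker, subtype_group = lab,
                             method = "fixed")
      out$selected <- "fixed"
      out$rationale <- if (identical(row$rule, "quantile")) {
        sprintf("quantile rule (q = %.2f) resolved from the data", row$quantile)
      } else "published cutoff applied without estimation"
      return(out)
    }
    med <- median_cutoff(sc)
    med_res <- evaluate_cutoff(sc, sub$time, sub$event, med,
                               biomarker = row$biomarker,
                               subtype_group = lab, method = "median")
    scan_res <- tryCatch(
      scan_optimum(scan_cutoffs(sc, sub$time, sub$event,
                                min_group_frac = min_group_frac,
                                biomarker = row$biomarker,
                                subtype_group = lab)),
      error = function(e) med_res)
    select_threshold(med_res, scan_res, alpha = alpha,
                     value_margin = value_margin,
                     score_range = diff(range(sc, na.rm = TRUE)))
  })
}
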
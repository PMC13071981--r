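# Outcome statistics: Kaplan-Meier estimation, Mantel-Cox log-rank with the
# observed/expected hazard ratio, Cox proportional-hazards regression,
# fixed-horizon ROC, Fisher's exact test, Kruskal-Wallis with Dunn's post
# hoc comparisons, and score correlations with qualitative strength bands.

check_surv <- function(times, events) {
  if (length(times) == 0) abort("Empty survival input.")
  if (length(times) != length(events)) {
    abort("`times` and `events` must have the same length.")
  }
  if (any(times < 0, na.rm = TRUE)) abort("`times` must be >= 0.")
  if (!all(events %in% c(0, 1, NA))) abort("`events` must be 0/1.")
  invisible(NULL)
}

#' Kaplan-Meier product-limit estimate
#'
#' Tidy wrapper around the product-limit estimator with right censoring;
#' survival starts at 1 at time 0 and is non-increasing.
#'
#' @param times Follow-up times in months.
#' @param events Event flags (1 = relapse, 0 = censored).
#' @param group Optional stratification factor.
#' @return A tibble of class `ihc_km`: `stratum`, `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`, `lower`, `upper`, including the
#'   time-zero row per stratum.
#' @export
km_estimate <- function(times, events, group = NULL) {
  check_surv(times, events)
  if (is.null(group)) group <- rep("all", length(times))
  fit <- survival::survfit(
    survival::Surv(times, events) ~ grp,
    data = data.frame(times = times, events = events, grp = group))
  smry <- summary(fit, censored = TRUE)
  stratum <- if (is.null(smry$strata)) rep(unique(as.character(group)),
                                           length(smry$time))
             else sub("^grp=", "", as.character(smry$strata))
  out <- tibble::tibble(
    stratum = stratum, time = smry$time, n_risk = smry$n.risk,
    n_event = smry$n.event, n_censor = smry$n.censor, surv = smry$surv,
    lower = smry$lower, upper = smry$upper)
  zero <- out |>
    dplyr::distinct(.data$stratum) |>
    dplyr::mutate(time = 0, n_risk = as.integer(table(group)[.data$stratum]),
                  n_event = 0L, n_censor = 0L, surv = 1,
                  lower = 1, upper = 1)
  out <- dplyr::bind_rows(zero, out) |>
    dplyr::arrange(.data$stratum, .data$time)
  class(out) <- c("ihc_km", class(out))
  out
}

#' Mantel-Cox log-rank test with observed/expected hazard ratio
#'
#' Two-group log-rank (Mantel-Cox) test.  The hazard ratio is the
#' observed/expected estimate \eqn{(O_t/E_t)/(O_r/E_r)} for the test group
#' versus the reference, with a log-scale confidence interval using
#' \eqn{SE(\log HR) = \sqrt{1/E_t + 1/E_r}} -- the "log-rank HR" convention
#' of common survival-graphing software.  When a group has zero events the
#' ratio is degenerate (0 or infinite); the result is flagged and the CI is
#' one-sided.
#'
#' @param times,events Follow-up times and event flags.
#' @param group Two-level grouping; the *last* level (or `test_level`) is
#'   the test group, so a hazard ratio below 1 means the test group is
#'   protected.
#' @param test_level Which level of `group` is the test group.
#' @param conf_level Confidence level of the hazard-ratio interval.
#' @return A one-row tibble of class `ihc_logrank`: `chi2`, `p`, `hr`,
#'   `hr_lower`, `hr_upper`, `n_test`, `n_ref`, `o_test`, `e_test`,
#'   `o_ref`, `e_ref`, `degenerate`.
#' @export
logrank_test <- function(times, events, group, test_level = NULL,
                         conf_level = 0.95) {
  check_surv(times, events)
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2) {
    abort("`group` must have exactly two levels with data.")
  }
  group <- droplevels(group)
  test_level <- test_level %||% levels(group)[2]
  if (!test_level %in% levels(group)) abort("`test_level` not in `group`.")
  ref_level <- setdiff(levels(group), test_level)
  sd <- survival::survdiff(
    survival::Surv(times, events) ~ grp,
    data = data.frame(times = times, events = events, grp = group))
  lev <- sub("^grp=", "", names(sd$n))
  it <- match(test_level, lev); ir <- match(ref_level, lev)
  o <- sd$obs; e <- sd$exp
  v <- if (is.matrix(sd$var)) sd$var[1, 1] else sd$var
  chi2 <- if (v > 0) (o[it] - e[it])^2 / v else 0
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  degenerate <- o[it] == 0 || o[ir] == 0
  hr <- (o[it] / e[it]) / (o[ir] / e[ir])
  z <- qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(1 / e[it] + 1 / e[ir])
  if (degenerate) {
    warn("A group has zero events; the hazard ratio is degenerate.")
    lo <- if (o[it] == 0) 0 else exp(log(hr) - z * se)
    up <- if (o[ir] == 0) Inf else exp(log(hr) + z * se)
  } else {
    lo <- exp(log(hr) - z * se)
    up <- exp(log(hr) + z * se)
  }
  out <- tibble::tibble(
    chi2 = unname(chi2), p = unname(p), hr = unname(hr),
    hr_lower = unname(lo), hr_upper = unname(up),
    n_test = unname(sd$n[it]), n_ref = unname(sd$n[ir]),
    o_test = unname(o[it]), e_test = unname(e[it]),
    o_ref = unname(o[ir]), e_ref = unname(e[ir]),
    degenerate = degenerate)
  class(out) <- c("ihc_logrank", class(out))
  out
}

#' Cox proportional-hazards regression
#'
#' Maximum partial likelihood with Efron tie handling and Wald confidence
#' intervals.  The design is checked for full column rank before fitting,
#' and coefficients drifting towards infinity (monotone likelihood /
#' separation) are flagged.
#'
#' @param times,events Follow-up times and event flags.
#' @param covariates A data frame or matrix of covariates (factors
#'   allowed in data frames).
#' @param conf_level Confidence level for the hazard-ratio intervals.
#' @return An object of class `ihc_cox`: the underlying
#'   [survival::coxph()] fit plus a tidy coefficient table; use [tidy()]
#'   and [glance()].
#' @export
cox_fit <- function(times, events, covariates, conf_level = 0.95) {
  check_surv(times, events)
  if (sum(events, na.rm = TRUE) < 1) abort("At least one event is required.")
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(times)) {
    abort("`covariates` must have one row per patient.")
  }
  mm <- stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
  if (qr(mm)$rank < ncol(mm)) {
    abort("Covariate design is rank deficient (collinear columns).")
  }
  df <- cbind(data.frame(.time = times, .event = events), covariates)
  fml <- stats::reformulate(sprintf("`%s`", names(covariates)),
                            response = "survival::Surv(.time, .event)")
  fit <- survival::coxph(fml, data = df, ties = "efron")
  z <- qnorm(1 - (1 - conf_level) / 2)
  co <- summary(fit)$coefficients
  separated <- any(abs(co[, "coef"]) > 15)
  if (separated) warn("Possible monotone likelihood: extreme coefficient(s).")
  tidy_tbl <- tibble::tibble(
    term = rownames(co),
    estimate = co[, "coef"],
    hr = exp(co[, "coef"]),
    hr_lower = exp(co[, "coef"] - z * co[, "se(coef)"]),
    hr_upper = exp(co[, "coef"] + z * co[, "se(coef)"]),
    p = co[, "Pr(>|z|)"])
  structure(list(fit = fit, coefficients = tidy_tbl,
                 converged = fit$info["convergence"] %||% TRUE,
                 iterations = fit$iter, separated = separated,
                 n = fit$n, n_events = fit$nevent),
            class = "ihc_cox")
}

#' @export
print.ihc_cox <- function(x, ...) {
  cat("Cox proportional-hazards fit (Efron ties): n =", x$n,
      ", events =", x$n_events, "\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.ihc_cox <- function(x, ...) x$coefficients

#' @export
glance.ihc_cox <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    n = x$n, n_events = x$n_events,
    logLik = as.numeric(stats::logLik(x$fit)),
    lr_statistic = unname(s$logtest["test"]),
    lr_p = unname(s$logtest["pvalue"]),
    concordance = unname(s$concordance["C"]),
    iterations = x$iterations, separated = x$separated)
}

#' Fixed-horizon ROC analysis of a prognostic score
#'
#' Binarises outcome at a follow-up horizon (relapse at or before the
#' horizon versus relapse-free) and evaluates a score as a classifier of
#' the relapse-free state: higher scores are expected in patients who do
#' not relapse.  Patients censored before the horizon without an event are
#' excluded by default (`censored = "exclude"`) because their class is
#' unknown; `censored = "negative"` instead counts them relapse-free.  With
#' `horizon = Inf` the outcome is the raw event flag regardless of time.
#'
#' The AUC is the Mann-Whitney rank statistic over relapse-free/relapsed
#' pairs (ties count half), with a Hanley-McNeil standard error for the
#' confidence interval.  Sensitivity here is the fraction of relapse-free
#' patients called relapse-free (score above the cutoff); specificity the
#' fraction of relapsed patients called relapsed.
#'
#' @param scores Prognostic score (higher = better expected outcome).
#' @param times,events Follow-up times and event flags.
#' @param horizon Months of follow-up defining the outcome; `Inf` uses the
#'   event flag as-is.
#' @param censored How to treat patients censored before the horizon.
#' @param cutoff Operating cutoff highlighted in the summary; a patient is
#'   called relapse-free when `score > cutoff`.
#' @param conf_level Confidence level for the AUC interval.
#' @return An object of class `ihc_roc` with fields `auc`, `auc_lower`,
#'   `auc_upper`, `p` (against AUC = 0.5), `horizon`, `n_relapse_free`,
#'   `n_relapsed`, `n_excluded`, `sensitivity`, `specificity`, `cutoff`,
#'   and an `operating_points` tibble.
#' @export
roc_at_horizon <- function(scores, times, events, horizon = 60,
                           censored = c("exclude", "negative"),
                           cutoff = 0, conf_level = 0.95) {
  censored <- match.arg(censored)
  check_surv(times, events)
  if (length(scores) != length(times)) abort("Input lengths differ.")
  if (!(horizon > 0)) abort("`horizon` must be > 0.")
  keep <- !is.na(scores) & !is.na(times) & !is.na(events)
  scores <- scores[keep]; times <- times[keep]; events <- events[keep]
  if (is.infinite(horizon)) {
    relapse <- events == 1
    excluded <- rep(FALSE, length(scores))
  } else {
    relapse <- events == 1 & times <= horizon
    unknown <- events == 0 & times < horizon
    excluded <- unknown & censored == "exclude"
    if (censored == "negative") relapse[unknown] <- FALSE
  }
  scores_u <- scores[!excluded]; relapse_u <- relapse[!excluded]
  n1 <- sum(!relapse_u); n0 <- sum(relapse_u)
  if (n1 == 0 || n0 == 0) {
    abort("One outcome class is empty at this horizon.")
  }
  # Mann-Whitney AUC via midranks: P(score_freer > score_relapsed) + .5 ties
  r <- rank(scores_u)
  auc <- (sum(r[!relapse_u]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # Hanley & McNeil (1982) SE
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- 2 * pnorm(-abs(auc - 0.5) / max(se, .Machine$double.eps))
  cuts <- sort(unique(c(scores_u, cutoff)))
  ops <- purrr::map_dfr(cuts, function(cc) {
    tibble::tibble(cutoff = cc,
                   sensitivity = mean(scores_u[!relapse_u] > cc),
                   specificity = mean(scores_u[relapse_u] <= cc))
  })
  at <- ops[ops$cutoff == cutoff, ]
  structure(list(
    auc = auc, auc_lower = max(0, auc - z * se),
    auc_upper = min(1, auc + z * se), p = p, horizon = horizon,
    n_relapse_free = n1, n_relapsed = n0, n_excluded = sum(excluded),
    cutoff = cutoff, sensitivity = at$sensitivity,
    specificity = at$specificity, operating_points = ops),
    class = "ihc_roc")
}

#' @export
print.ihc_roc <- function(x, ...) {
  cat(sprintf(
    "ROC at horizon %s months: AUC %.4f [%.4f, %.4f], p = %.3g\n",
    format(x$horizon), x$auc, x$auc_lower, x$auc_upper, x$p))
  cat(sprintf(
    "At cutoff %g: sensitivity %.0f%%, specificity %.0f%% (%d relapse-free, %d relapsed, %d excluded)\n",
    x$cutoff, 100 * x$sensitivity, 100 * x$specificity,
    x$n_relapse_free, x$n_relapsed, x$n_excluded))
  invisible(x)
}

#' @export
tidy.ihc_roc <- function(x, ...) x$operating_points

#' @export
glance.ihc_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, auc_lower = x$auc_lower,
                 auc_upper = x$auc_upper, p = x$p, horizon = x$horizon,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 n_relapse_free = x$n_relapse_free,
                 n_relapsed = x$n_relapsed, n_excluded = x$n_excluded)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' @param tab A 2x2 matrix (or object coercible to one) of non-negative
#'   counts.
#' @return A one-row tibble: `p`, `odds_ratio`, `or_lower`, `or_upper`.
#' @export
fisher_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) abort("`tab` must be 2x2.")
  if (any(tab < 0)) abort("Counts must be non-negative.")
  ft <- fisher.test(tab)
  tibble::tibble(p = ft$p.value, odds_ratio = unname(ft$estimate),
                 or_lower = ft$conf.int[1], or_upper = ft$conf.int[2])
}

#' Multi-group rank comparison with Dunn's post hoc test
#'
#' Kruskal-Wallis test across groups followed by Dunn's pairwise z tests on
#' mean ranks (with the tie correction), multiplicity-adjusted (Bonferroni
#' by default, matching the classical Dunn correction).
#'
#' @param values Numeric vector of scores.
#' @param groups Grouping factor.
#' @param adjust Multiplicity adjustment passed to [stats::p.adjust()].
#' @return A list of class `ihc_groupcmp` with `overall` (a one-row tibble:
#'   `statistic`, `df`, `p`) and `pairwise` (tibble: `group1`, `group2`,
#'   `z`, `p`, `p_adjusted`).
#' @export
group_compare <- function(values, groups, adjust = "bonferroni") {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- droplevels(as.factor(groups[keep]))
  if (nlevels(groups) < 2) abort("Need at least two groups with data.")
  kw <- kruskal.test(values, groups)
  n <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ni <- tapply(r, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  s2 <- n * (n + 1) / 12 - tie_term
  pairs <- utils::combn(levels(groups), 2)
  pw <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    z <- (rbar[[a]] - rbar[[b]]) /
      sqrt(s2 * (1 / ni[[a]] + 1 / ni[[b]]))
    tibble::tibble(group1 = a, group2 = b, z = z,
                   p = 2 * pnorm(-abs(z)))
  })
  pw$p_adjusted <- stats::p.adjust(pw$p, method = adjust)
  structure(list(
    overall = tibble::tibble(statistic = unname(kw$statistic),
                             df = unname(kw$parameter),
                             p = kw$p.value),
    pairwise = pw), class = "ihc_groupcmp")
}

#' @export
print.ihc_groupcmp <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis chi2 = %.3f, df = %d, p = %.3g\n",
              x$overall$statistic, x$overall$df, x$overall$p))
  print(x$pairwise)
  invisible(x)
}

#' @export
tidy.ihc_groupcmp <- function(x, ...) x$pairwise

#' @export
glance.ihc_groupcmp <- function(x, ...) x$overall

#' Correlation between two score vectors with a strength band
#'
#' Correlation coefficient, p value and a qualitative strength band:
#' `|r| < 0.4` weak, `0.4 <= |r| <= 0.7` moderate, `|r| > 0.7` strong.
#'
#' @param x,y Numeric vectors.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A one-row tibble: `r`, `p`, `band`, `n`, `method`.
#' @export
score_correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  keep <- complete.cases(x, y)
  ct <- cor.test(x[keep], y[keep], method = method, exact = FALSE)
  r <- unname(ct$estimate)
  tibble::tibble(r = r, p = ct$p.value, band = correlation_band(r),
                 n = sum(keep), method = method)
}

correlation_band <- function(r) {
  dplyr::case_when(
    is.na(r) ~ NA_character_,
    abs(r) < 0.4 ~ "weak",
    abs(r) <= 0.7 ~ "moderate",
    TRUE ~ "strong")
}
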
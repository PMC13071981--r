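test_that("median cutoff is the sample median with a degeneracy flag", {
  expect_equal(as.numeric(median_cutoff(c(1, 2, 3))), 2)
  expect_equal(as.numeric(median_cutoff(c(1, 2, 3, 4))), 2.5)
  expect_false(attr(median_cutoff(c(1, 2, 3)), "degenerate"))
  const <- median_cutoff(c(5, 5, 5))
  expect_true(attr(const, "degenerate"))
  expect_error(median_cutoff(c(NA, 1)), "two non-missing")
})

test_that("a degenerate cutoff leaves all patients on one side", {
  res <- evaluate_cutoff(rep(5, 20), rexp(20) * 0 + 1:20,
                         rep(1, 20), cutoff = 5)
  expect_true(res$degenerate)
  expect_equal(res$n_low, 0)
})

test_that("perfect separation puts the scan optimum at the separating midpoint", {
  # low scores all relapse (at one early time); high scores never relapse
  scores <- c(1:10, 21:30)
  times <- c(rep(5, 10), rep(100, 10))
  events <- c(rep(1, 10), rep(0, 10))
  scan <- scan_cutoffs(scores, times, events, min_group_frac = 0.1)
  opt <- scan_optimum(scan)
  expect_equal(opt$cutoff, (10 + 21) / 2)
  expect_lt(opt$hr, 1)
  expect_lt(opt$logrank_p, 0.001)
})

test_that("the scan optimum attains the minimum over returned candidates", {
  withr::with_seed(5, {
    scores <- rnorm(40)
    times <- rexp(40, 0.02)
    events <- rbinom(40, 1, 0.7)
  })
  scan <- scan_cutoffs(scores, times, events)
  opt <- scan_optimum(scan)
  expect_equal(opt$logrank_p, min(scan$logrank_p, na.rm = TRUE))
  # group-size floor is respected
  n <- sum(!is.na(scores))
  expect_true(all(scan$n_high >= ceiling(0.1 * n)))
  expect_true(all(scan$n_low >= ceiling(0.1 * n)))
})

test_that("scan optimum equals exhaustive brute force on small instances", {
  # oracle: evaluate every admissible distinct-value split directly with
  # survival::survdiff, independent of the scan implementation
  brute_force <- function(scores, times, events, min_frac) {
    uniq <- sort(unique(scores))
    cand <- (head(uniq, -1) + uniq[-1]) / 2
    n <- length(scores)
    best <- NULL
    for (cc in cand) {
      nh <- sum(scores >= cc)
      if (min(nh, n - nh) < ceiling(min_frac * n)) next
      sd <- survival::survdiff(survival::Surv(times, events) ~ I(scores >= cc))
      p <- stats::pchisq(sd$chisq, 1, lower.tail = FALSE)
      if (is.null(best) || p < best$p - 1e-12 ||
          (abs(p - best$p) <= 1e-12 &&
           abs(cc - median(scores)) < abs(best$cut - median(scores)))) {
        best <- list(cut = cc, p = p)
      }
    }
    best
  }
  for (seed in 1:8) {
    withr::with_seed(seed, {
      n <- sample(12:30, 1)
      scores <- round(rnorm(n, 50, 20), 1)
      times <- round(rexp(n, 0.03), 2)
      events <- rbinom(n, 1, 0.6)
    })
    if (sum(events) < 2) next
    oracle <- brute_force(scores, times, events, 0.1)
    opt <- scan_optimum(scan_cutoffs(scores, times, events,
                                     min_group_frac = 0.1))
    expect_equal(opt$cutoff, oracle$cut)
    expect_equal(opt$logrank_p, oracle$p, tolerance = 1e-8)
  }
})

test_that("cutoff scanning on null data is optimistic", {
  # scores independent of survival: the minimal p over the scan
  # concentrates well below its nominal level
  p_min <- vapply(1:60, function(s) {
    withr::with_seed(s, {
      scores <- rnorm(60)
      times <- rexp(60, 0.02)
      events <- rbinom(60, 1, 0.7)
    })
    scan_optimum(scan_cutoffs(scores, times, events))$logrank_p
  }, numeric(1))
  expect_gt(mean(p_min < 0.05), 0.15)  # far above the nominal 5%
  expect_lt(median(p_min), 0.25)
})

test_that("relabelling high and low inverts the hazard ratio", {
  withr::with_seed(3, {
    times <- rexp(60, 0.03)
    events <- rbinom(60, 1, 0.8)
    high <- rbinom(60, 1, 0.5) == 1
  })
  grp <- factor(high, c(FALSE, TRUE), c("low", "high"))
  a <- logrank_test(times, events, grp, test_level = "high")
  b <- logrank_test(times, events, grp, test_level = "low")
  expect_equal(a$hr, 1 / b$hr, tolerance = 1e-12)
  expect_equal(a$p, b$p)
})

test_that("threshold selection follows the published policy", {
  mk <- function(p, cutoff, method) {
    res <- tibble::tibble(
      biomarker = "PTEN", subtype_group = "g", method = method,
      cutoff = cutoff, n_high = 10L, n_low = 10L, logrank_p = p,
      hr = 0.5, hr_lower = 0.2, hr_upper = 0.9, degenerate = FALSE,
      note = NA_character_)
    class(res) <- c("ihc_threshold", class(res))
    res
  }
  # significant median wins regardless of the scan
  sel <- select_threshold(mk(0.01, 100, "median"), mk(0.001, 150, "scan"))
  expect_equal(sel$selected, "median")
  # non-significant median, notably different significant scan: scan wins
  sel <- select_threshold(mk(0.4, 100, "median"), mk(0.01, 150, "scan"))
  expect_equal(sel$selected, "scan")
  expect_equal(sel$cutoff, 150)
  # neither significant: median kept, flagged non-informative
  sel <- select_threshold(mk(0.4, 100, "median"), mk(0.2, 150, "scan"))
  expect_equal(sel$selected, "median")
  expect_equal(sel$note, "non-informative")
  # significant scan too close to the median to count as different
  sel <- select_threshold(mk(0.4, 100, "median"), mk(0.01, 101, "scan"))
  expect_equal(sel$selected, "median")
})

test_that("shipped fixed thresholds carry the published cutoffs", {
  th <- default_thresholds()
  expect_equal(th$cutoff[th$biomarker == "TOP2A"], 45)
  expect_equal(th$cutoff[th$biomarker == "PTEN"], 100)
  expect_equal(th$cutoff[th$biomarker == "IGF1R"], 219)
  expect_equal(th$cutoff[th$biomarker == "pmTOR_wholecell"], 100)
  expect_equal(th$cutoff[th$biomarker == "pmTOR_perinuclear"], 1)
  expect_equal(th$rule[th$biomarker == "EGFR"], "quantile")
})

test_that("estimate_thresholds applies fixed cutoffs without estimation", {
  co <- simulate_cohort(sim_config(n_patients = 400, seed = 21))
  th <- estimate_thresholds(co, policy = "fixed")
  expect_equal(nrow(th), 6)
  expect_true(all(th$selected == "fixed"))
  expect_equal(th$cutoff[th$biomarker == "TOP2A"], 45)
  # the EGFR quantile rule resolves from the non-Luminal-A pool
  pool <- co[co$subtype != "LuminalA", ]
  expect_equal(th$cutoff[th$biomarker == "EGFR"],
               unname(quantile(pool$egfr, 0.95, na.rm = TRUE)))
})
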
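test_that("KM with no censoring equals the empirical survivor function", {
  times <- c(2, 4, 4, 7, 9, 12)
  km <- km_estimate(times, rep(1, 6))
  emp <- vapply(km$time, function(t) mean(times > t), numeric(1))
  expect_equal(km$surv, emp)
  expect_equal(km$surv[km$time == 0], 1)
  expect_true(all(diff(km$surv) <= 1e-12))
})

test_that("KM with all observations censored stays at 1", {
  km <- km_estimate(c(3, 6, 9), c(0, 0, 0))
  expect_true(all(km$surv == 1))
})

test_that("KM matches the hand product-limit on a censored fixture", {
  # times 1, 2, 3 with events 1, 1, 0:
  # S(1) = 2/3, S(2) = 2/3 * 1/2 = 1/3, censoring at 3 leaves S = 1/3
  km <- km_estimate(c(1, 2, 3), c(1, 1, 0))
  expect_equal(km$surv[km$time == 1], 2 / 3)
  expect_equal(km$surv[km$time == 2], 1 / 3)
  expect_equal(km$surv[km$time == 3], 1 / 3)
  # deeper fixture with a censor interleaved: 1+, 2, 2, 4
  # S(2) = 1 * (3-2)/3 = 1/3 ; S(4) = 1/3 * 0 = 0
  km2 <- km_estimate(c(1, 2, 2, 4), c(0, 1, 1, 1))
  expect_equal(km2$surv[km2$time == 2], 1 / 3)
  expect_equal(km2$surv[km2$time == 4], 0)
})

test_that("log-rank on identical groups is null and label-symmetric", {
  times <- rep(c(1, 3, 5, 7), 2)
  events <- rep(c(1, 1, 0, 1), 2)
  grp <- rep(c("a", "b"), each = 4)
  lr <- logrank_test(times, events, grp)
  expect_equal(lr$chi2, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1, tolerance = 1e-12)
  expect_equal(lr$hr, 1, tolerance = 1e-12)
})

test_that("log-rank p is consistent with the exact permutation distribution", {
  fixtures <- list(
    list(times = c(1, 2, 3, 5, 6, 8, 9, 11, 12, 13),
         events = c(1, 1, 1, 0, 1, 1, 0, 1, 1, 1), n_test = 5),
    list(times = c(2, 2, 4, 5, 7, 7, 8, 10, 12, 14, 15, 16),
         events = c(1, 0, 1, 1, 1, 1, 0, 1, 1, 0, 1, 1), n_test = 6),
    list(times = c(1, 4, 4, 6, 9, 10, 12, 15),
         events = c(1, 1, 1, 1, 1, 0, 1, 1), n_test = 4))
  for (fx in fixtures) {
    n <- length(fx$times)
    # a fixed, arbitrary assignment of patients to arms
    in_test <- seq_len(n) %in% seq(1, n, by = 2)[seq_len(fx$n_test)]
    grp <- factor(in_test, c(FALSE, TRUE), c("ref", "test"))
    lr <- suppressWarnings(logrank_test(fx$times, fx$events, grp,
                                        test_level = "test"))
    perm_p_fun <- logrank_permutation_p(fx$times, fx$events, fx$n_test)
    # the oracle recomputes the statistic by hand; check both routes agree
    expect_equal(lr$chi2,
                 logrank_chi2_by_hand(fx$times, fx$events, in_test),
                 tolerance = 1e-9)
    p_perm <- perm_p_fun(lr$chi2)
    expect_lt(abs(lr$p - p_perm), 0.1)
  }
})

test_that("swapping log-rank group labels inverts the hazard ratio", {
  withr::with_seed(11, {
    times <- rexp(40, 0.05)
    events <- rbinom(40, 1, 0.8)
    grp <- factor(sample(c("low", "high"), 40, TRUE), c("low", "high"))
  })
  a <- logrank_test(times, events, grp, test_level = "high")
  b <- logrank_test(times, events, grp, test_level = "low")
  expect_equal(a$hr * b$hr, 1, tolerance = 1e-12)
  expect_equal(a$p, b$p)
  expect_equal(a$chi2, b$chi2)
})

test_that("zero events in a group flags a degenerate hazard ratio", {
  times <- c(1, 2, 3, 10, 11, 12)
  events <- c(1, 1, 1, 0, 0, 0)
  grp <- factor(rep(c("ref", "test"), each = 3), c("ref", "test"))
  expect_warning(lr <- logrank_test(times, events, grp), "zero events")
  expect_true(lr$degenerate)
  expect_equal(lr$hr, 0)
  expect_equal(lr$hr_lower, 0)
})

test_that("Cox and log-rank hazard ratios agree asymptotically", {
  withr::with_seed(19, {
    n <- 3000
    x <- rbinom(n, 1, 0.5)
    t <- rexp(n, 0.02 * exp(log(0.4) * x))
    cens <- pmin(t, 80)
    ev <- as.integer(t <= 80)
  })
  lr <- logrank_test(cens, ev, factor(x, 0:1, c("low", "high")))
  cx <- cox_fit(cens, ev, data.frame(high = x))
  expect_equal(tidy(cx)$hr, lr$hr, tolerance = 0.05)
  expect_lt(abs(tidy(cx)$hr - 0.4), 0.08)
})

test_that("a null covariate's CI covers 1 at roughly the nominal rate", {
  cover <- vapply(1:40, function(s) {
    withr::with_seed(s, {
      x <- rbinom(150, 1, 0.5)
      t <- rexp(150, 0.03)
      ev <- as.integer(t <= 60)
      t <- pmin(t, 60)
    })
    td <- tidy(cox_fit(t, ev, data.frame(x = x)))
    td$hr_lower <= 1 && td$hr_upper >= 1
  }, logical(1))
  expect_gte(mean(cover), 0.85)
})

test_that("a rank-deficient Cox design is rejected", {
  withr::with_seed(2, {
    x <- rbinom(50, 1, 0.5)
    t <- rexp(50, 0.05)
  })
  expect_error(cox_fit(t, rep(1, 50), data.frame(a = x, b = x)),
               "rank deficient")
  expect_error(cox_fit(t, rep(0, 50), data.frame(a = x)), "event")
})

test_that("ROC AUC equals brute-force pair counting on a toy table", {
  scores <- c(3, 2, 1, 0, -1, -2)
  times <- c(70, 70, 30, 70, 20, 10)
  events <- c(0, 0, 1, 0, 1, 1)
  roc <- roc_at_horizon(scores, times, events, horizon = 60)
  # all-pairs oracle: relapse-free {3,2,0}, relapsed {1,-1,-2}
  free <- scores[c(1, 2, 4)]; rel <- scores[c(3, 5, 6)]
  pairs <- expand.grid(f = free, r = rel)
  auc_brute <- mean(ifelse(pairs$f > pairs$r, 1,
                           ifelse(pairs$f == pairs$r, 0.5, 0)))
  expect_equal(roc$auc, auc_brute)
  # sensitivity/specificity at the score > 0 call
  expect_equal(roc$sensitivity, 2 / 3)  # scores 3, 2 of the free three
  expect_equal(roc$specificity, 2 / 3)  # relapsers -1, -2 called; 1 missed
})

test_that("ROC boundary behaviours hold", {
  scores <- c(5, 4, 3, -3, -4, -5)
  times <- rep(c(100, 10), each = 3)
  events <- rep(c(0, 1), each = 3)
  expect_equal(roc_at_horizon(scores, times, events, 60)$auc, 1)
  expect_equal(roc_at_horizon(rep(1, 6), times, events, 60)$auc, 0.5)
  # censored-before-horizon patients are excluded by default
  times2 <- c(30, 100, 100, 10, 10, 10)
  roc <- roc_at_horizon(scores, times2, events, 60)
  expect_equal(roc$n_excluded, 1)
  roc_neg <- roc_at_horizon(scores, times2, events, 60,
                            censored = "negative")
  expect_equal(roc_neg$n_excluded, 0)
  expect_equal(roc_neg$n_relapse_free, 3)
  # an infinite horizon uses the raw event flag
  roc_any <- roc_at_horizon(scores, times2, events, Inf)
  expect_equal(roc_any$n_relapse_free + roc_any$n_relapsed, 6)
  expect_error(roc_at_horizon(scores, rep(100, 6), rep(0, 6), 60),
               "class is empty")
})

test_that("ROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(23, {
    scores <- rnorm(80)
    relapse <- rbinom(80, 1, plogis(-scores))
    times <- ifelse(relapse == 1, runif(80, 1, 59), 100)
  })
  roc <- roc_at_horizon(scores, times, relapse, horizon = 60)
  ref <- pROC::roc(response = relapse, predictor = scores,
                   direction = ">", quiet = TRUE)
  expect_equal(roc$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  res <- fisher_2x2(matrix(c(5, 0, 0, 5), 2))
  expect_equal(res$p, 2 / choose(10, 5), tolerance = 1e-12)
  expect_error(fisher_2x2(matrix(1:6, 2)), "2x2")
  expect_error(fisher_2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("group comparison reproduces Kruskal-Wallis and flags pairs", {
  withr::with_seed(31, {
    g <- rep(c("a", "b", "c"), each = 30)
    v <- rnorm(90) + rep(c(0, 0, 2), each = 30)
  })
  gc <- group_compare(v, g)
  kw <- kruskal.test(v, factor(g))
  expect_equal(gc$overall$p, kw$p.value)
  expect_equal(gc$overall$statistic, unname(kw$statistic))
  pw <- tidy(gc)
  expect_equal(nrow(pw), 3)
  # the separated group differs from both others after adjustment
  sig <- pw$p_adjusted[pw$group1 == "a" & pw$group2 == "c"]
  expect_lt(sig, 0.01)
  nul <- pw$p_adjusted[pw$group1 == "a" & pw$group2 == "b"]
  expect_gt(nul, 0.05)
  expect_true(all(pw$p_adjusted >= pw$p))
})

test_that("Dunn z statistics follow the tie-corrected mean-rank formula", {
  # tiny fixture computed by direct arithmetic
  v <- c(1, 2, 3, 4, 5, 6)
  g <- rep(c("x", "y"), each = 3)
  gc <- group_compare(v, g)
  r <- rank(v)
  z_hand <- (mean(r[1:3]) - mean(r[4:6])) /
    sqrt((6 * 7 / 12) * (1 / 3 + 1 / 3))
  expect_equal(tidy(gc)$z, z_hand)
})

test_that("correlation strength bands follow the published labelling", {
  expect_equal(score_correlation(1:10, (1:10) * 2)$r, 1)
  expect_equal(score_correlation(1:10, (1:10) * 2)$band, "strong")
  expect_equal(ihcsig:::correlation_band(0.6559), "moderate")
  expect_equal(ihcsig:::correlation_band(0.3968), "weak")
  expect_equal(ihcsig:::correlation_band(0.6907), "moderate")
  expect_equal(ihcsig:::correlation_band(-0.8), "strong")
  withr::with_seed(1, {
    x <- rnorm(50); y <- 0.7 * x + rnorm(50)
  })
  ref <- cor.test(x, y)
  sc <- score_correlation(x, y)
  expect_equal(sc$r, unname(ref$estimate))
  expect_equal(sc$p, ref$p.value)
})
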
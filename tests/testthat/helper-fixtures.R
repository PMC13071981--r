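# Fixture builders shared across the suite.  Everything is generated in
# code; no stored data.

# A minimal cell table: `n_by_intensity[k+1]` tumour cells at intensity k
# (placed mid-bin for the default thresholds), plus optional stroma cells.
make_cells <- function(n_by_intensity, n_stroma = 0, core_id = "c1",
                       patient_id = 1L, od_bins = default_od_bins()) {
  max_int <- length(n_by_intensity) - 1L
  mid <- c((c(0, od_bins) + c(od_bins, od_bins[max_int] + 0.4)) / 2)
  od <- rep(mid, times = n_by_intensity)
  n <- length(od)
  tibble::tibble(
    patient_id = patient_id, core_id = core_id,
    cell_class = c(rep("tumour", n), rep("stroma", n_stroma)),
    od_nuclear = c(od, rep(0.05, n_stroma)),
    od_cytoplasm = c(od, rep(0.05, n_stroma)),
    od_perinuclear = c(od, rep(0.05, n_stroma)),
    od_cell = c(od, rep(0.05, n_stroma)))
}

# A complete subtype-marker row.
make_markers <- function(er_percent = 0, er_intensity = 0,
                         pr_percent = 0, pr_intensity = 0,
                         her2 = FALSE, ki67 = 0) {
  tibble::tibble(er_percent = er_percent, er_intensity = er_intensity,
                 pr_percent = pr_percent, pr_intensity = pr_intensity,
                 her2_positive = her2, ki67_percent = ki67)
}

# Hand-coded log-rank statistic (hypergeometric O-E sums) independent of
# survival::survdiff; used as the permutation oracle's engine.
logrank_chi2_by_hand <- function(times, events, in_test) {
  dt <- sort(unique(times[events == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in dt) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & in_test)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & in_test)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) {
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  if (v <= 0) return(0)
  o_minus_e^2 / v
}

# Exact permutation p of the log-rank statistic over all assignments of
# `n_test` patients to the test arm.
logrank_permutation_p <- function(times, events, n_test) {
  n <- length(times)
  combos <- utils::combn(n, n_test)
  stats <- apply(combos, 2, function(idx) {
    in_test <- seq_len(n) %in% idx
    logrank_chi2_by_hand(times, events, in_test)
  })
  function(observed_chi2) mean(stats >= observed_chi2 - 1e-9)
}
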
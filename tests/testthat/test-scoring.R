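test_that("intensity binning counts thresholds at or below the density", {
  bins <- default_od_bins()
  expect_equal(bin_intensity(0, bins), 0L)
  expect_equal(bin_intensity(0.45, bins), 2L)
  expect_equal(bin_intensity(5, bins), 3L)
  expect_equal(bin_intensity(0.2, bins), 1L)   # right-open: threshold counts
  expect_equal(bin_intensity(10, default_od_bins(4)), 4L)
  # monotone non-decreasing in density
  x <- sort(runif(200, 0, 1))
  expect_true(all(diff(bin_intensity(x, bins)) >= 0))
  expect_error(bin_intensity(-0.1, bins), ">= 0")
})

test_that("core QC excludes below 100 tumour cells and keeps 100", {
  fail <- make_cells(c(99, 0, 0, 0), n_stroma = 500)
  pass <- make_cells(c(100, 0, 0, 0))
  expect_false(qc_core(fail))
  expect_true(qc_core(pass))
  expect_false(qc_core(make_cells(c(0, 0, 0, 0))))
  two_cores <- dplyr::bind_rows(make_cells(c(50, 0, 0, 0), core_id = "a"),
                                make_cells(c(60, 0, 0, 0), core_id = "b"))
  expect_error(qc_core(two_cores), "single core")
})

test_that("percent positive is the share of intensity >= 1 tumour cells", {
  expect_equal(percent_positive(make_cells(c(100, 0, 0, 0))), 0)
  expect_equal(percent_positive(make_cells(c(0, 50, 30, 20))), 100)
  expect_equal(percent_positive(make_cells(c(90, 10, 10, 10))), 25)
  # stroma never contributes
  expect_equal(percent_positive(make_cells(c(90, 10, 10, 10),
                                           n_stroma = 400)), 25)
  expect_error(percent_positive(make_cells(c(0, 0, 0, 0), n_stroma = 10)),
               "empty core")
})

test_that("H-score is the intensity-weighted percent sum", {
  spec3 <- biomarker_specs()[2, ]
  expect_equal(h_score(make_cells(c(0, 50, 25, 25)), spec3), 175)
  expect_equal(h_score(make_cells(c(120, 0, 0, 0)), spec3), 0)
  expect_equal(h_score(make_cells(c(0, 0, 0, 100)), spec3), 300)
  spec4 <- biomarker_specs(max_intensity = c(PTEN = 4))[2, ]
  expect_equal(h_score(make_cells(c(40, 10, 20, 30, 0),
                                  od_bins = default_od_bins(4)), spec4), 140)
})

test_that("H-score equals percent positive when all positives are intensity 1", {
  cells <- make_cells(c(70, 30, 0, 0))
  expect_equal(h_score(cells), percent_positive(cells))
})

test_that("scores are invariant to cell-table row order", {
  cells <- make_cells(c(40, 30, 20, 30))
  shuffled <- cells[withr::with_seed(1, sample(nrow(cells))), ]
  expect_equal(h_score(shuffled), h_score(cells))
  expect_equal(percent_positive(shuffled), percent_positive(cells))
})

test_that("score_cells scores every core x biomarker with QC flags", {
  cells <- dplyr::bind_rows(
    make_cells(c(60, 20, 10, 10), core_id = "good"),
    make_cells(c(30, 10, 5, 5), core_id = "small"))
  cs <- score_cells(cells)
  expect_equal(nrow(cs), 2 * length(biomarker_names()))
  good <- cs[cs$core_id == "good", ]
  expect_true(all(good$qc_pass))
  expect_true(all(is.na(cs$value[cs$core_id == "small"])))
  # percent-positive biomarkers carry no H-score
  expect_true(all(is.na(good$h_score[good$method == "percent_positive"])))
  expect_true(all(!is.na(good$h_score[good$method == "h_score"])))
  # col_map absorbs a foreign export dialect
  foreign <- dplyr::rename(cells, Cell.DAB.OD = "od_cell")
  cs2 <- score_cells(foreign, col_map = c(od_cell = "Cell.DAB.OD"))
  expect_equal(cs2$value, cs$value)
})

test_that("patient aggregation averages QC-passing cores only", {
  cs <- tibble::tibble(
    patient_id = 1L, core_id = c("a", "b", "c"), biomarker = "PTEN",
    qc_pass = c(TRUE, TRUE, TRUE), value = c(100, 150, 200))
  expect_equal(aggregate_patient(cs)$value, 150)
  cs$qc_pass <- c(TRUE, FALSE, FALSE)
  expect_equal(aggregate_patient(cs)$value, 100)
  cs$qc_pass <- c(FALSE, FALSE, FALSE)
  agg <- aggregate_patient(cs)
  expect_true(is.na(agg$value))
  expect_equal(agg$n_cores_pass, 0)
  # median aggregation is available
  cs2 <- tibble::tibble(patient_id = 1L, core_id = c("a", "b", "c"),
                        biomarker = "PTEN", qc_pass = TRUE,
                        value = c(100, 110, 300))
  expect_equal(aggregate_patient(cs2, agg = "median")$value, 110)
})

test_that("simulate -> score round-trip recovers the intensity mixture", {
  mix <- c(0.4, 0.3, 0.2, 0.1)
  cells <- simulate_cells(50000, mix, tumour_fraction = 1, seed = 13)
  spec <- biomarker_specs()[2, ]
  expected_h <- sum((0:3) * mix) * 100
  expect_lt(abs(h_score(cells, spec) - expected_h), 2)
  expect_lt(abs(percent_positive(cells, spec) - 60), 1)
})
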
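tb13 <- default_timebase()

test_that("extract_trace recovers planted signal under uniform background", {
  p <- ideal_params()
  f <- simulate_field(1, c(80, 80), sim_params(responder_fraction = 1), seed = 7)
  f$y <- 40; f$x <- 40
  calcium <- matrix(0.3, 1, 13)
  st <- render_stack(f, calcium, tb13, p)
  mask <- st$truth$cell_labels == 1L
  tr <- extract_trace(st, mask)
  r_true <- sensor_ratio(0.3, p$sensor)
  expect_equal(tr$ratio, rep(r_true, 13), tolerance = 1e-10)
  # corrected means equal the planted cell-only signal
  expect_equal(tr$donor, rep(p$sensor$total / (1 + r_true), 13), tolerance = 1e-9)
  expect_error(extract_trace(st, matrix(FALSE, 80, 80)), "empty")
})

test_that("dF/F0 normalization follows (F - F0)/F0", {
  tr <- make_trace(c(2, 2, 2, 5, rep(2, 9)))
  tr <- normalize_trace(tr, tb13)
  expect_equal(tr$f0, 2)
  expect_equal(tr$dff[4], 1.5)
  expect_equal(tr$dff[1:3], rep(0, 3))
  # constant ratio -> all-zero dff
  trc <- normalize_trace(make_trace(rep(3.3, 13)), tb13)
  expect_equal(trc$dff, rep(0, 13))
  # no pre-dispense frames is impossible to construct: the timebase refuses
  expect_error(timebase(seq(0, 12), 0L), "n_pre")
  # f0 <= 0 invalidates the trace
  neg <- normalize_trace(make_trace(c(-1, -1, -1, rep(1, 10))), tb13)
  expect_false(neg$valid)
})

test_that("dF/F0 is invariant to common channel scaling", {
  tr <- make_trace(c(2, 2, 2, 5, 4, 3, rep(2, 7)))
  tr <- normalize_trace(tr, tb13)
  tr2 <- make_trace(tr$ratio, donor = tr$donor * 7.3)
  tr2 <- normalize_trace(tr2, tb13)
  expect_equal(tr2$dff, tr$dff)
})

test_that("peak amplitude uses only the post-dispense window", {
  tr <- make_trace(rep(1, 13))
  tr$dff <- c(0, 0, 0, 0.2, 1.1, 0.6, rep(0, 7)); tr$valid <- TRUE
  expect_equal(peak_amplitude(tr, tb13), 1.1)
  tr$dff <- rep(0, 13)
  expect_equal(peak_amplitude(tr, tb13), 0)
  tr$dff <- c(9, 0, 0, 0.3, rep(0, 9))  # pre-dispense spike ignored
  expect_equal(peak_amplitude(tr, tb13), 0.3)
})

test_that("responsiveness threshold is inclusive at the boundary", {
  expect_false(classify_responsive(0))
  expect_true(classify_responsive(0.1, threshold = 0.1))
  expect_false(classify_responsive(0.0999, threshold = 0.1))
  expect_error(classify_responsive(0.5, threshold = 0), "positive")
})

test_that("well summaries aggregate counts, fraction and responsive peak", {
  trs <- lapply(1:25, function(i) {
    tr <- make_trace(rep(2, 13))
    tr$ratio[5] <- 2 * (1 + 0.8)  # dff peak 0.8 for all
    tr
  })
  wr <- summarize_well(trs, tb13, well_id = "B02")
  expect_equal(wr$n_cells, 25L)
  expect_equal(wr$responsive_fraction, 1)
  expect_equal(wr$mean_peak_responsive, 0.8)
  expect_equal(wr$sd_peak_responsive, 0)
  # 100 cells, 29 responsive -> fraction 0.29
  trs2 <- lapply(1:100, function(i) {
    tr <- make_trace(rep(2, 13))
    if (i <= 29) tr$ratio[5] <- 2 * 1.5
    tr
  })
  wr2 <- summarize_well(trs2, tb13)
  expect_equal(wr2$responsive_fraction, 0.29)
  # below the responsive-cell QC floor -> invalid
  wr3 <- summarize_well(trs[1:5], tb13, min_responsive_cells = 20L)
  expect_false(wr3$valid)
  expect_true(is.na(wr3$mean_peak_responsive))
  expect_false(summarize_well(list(), tb13)$valid)
})

test_that("threshold calibration hits a target responsive fraction", {
  peaks <- seq(0, 1, length.out = 101)
  th <- calibrate_threshold(peaks, 0.29)
  expect_lt(abs(mean(peaks >= th) - 0.29), 0.011)
})

test_that("measured well peak increases with planted amplitude and is ~3x for FAD", {
  p1 <- ideal_params(genotype_amplitude = 1)
  p3 <- ideal_params(genotype_amplitude = 3)
  pk <- function(p) analyze_well(simulate_well(p, seed = 12),
                                 min_responsive_cells = 5L)$mean_peak_responsive
  r <- pk(p3) / pk(p1)
  expect_equal(r, 3, tolerance = 0.1)
})

test_that("measured normalized response tracks 1 - suppression monotonically", {
  p <- ideal_params()
  supp <- seq(0, 0.6, length.out = 8)
  peaks <- vapply(supp, function(s)
    analyze_well(simulate_well(p, seed = 13, suppression = s, n_cells = 25),
                 min_responsive_cells = 5L)$mean_peak_responsive, numeric(1))
  expect_equal(stats::cor(peaks, 1 - supp, method = "spearman"), 1)
})
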
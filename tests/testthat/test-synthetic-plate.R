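test_that("simulate_field places the requested cells with spacing and flags", {
  expect_equal(nrow(simulate_field(0, c(100, 100), sim_params(), seed = 1)), 0L)
  p <- sim_params(responder_fraction = 1)
  f <- simulate_field(50, c(300, 300), p, seed = 2)
  expect_equal(nrow(f), 50L)
  expect_true(all(f$is_responder))
  d <- as.matrix(stats::dist(f[, c("y", "x")]))
  diag(d) <- Inf
  expect_true(min(d) >= p$min_spacing)
  # impossible packing fails explicitly
  expect_error(simulate_field(200, c(50, 50), p, seed = 1), "packing")
})

test_that("planted responder fraction is recovered across seeds", {
  p <- sim_params("WT")  # responder_fraction 0.29
  fracs <- vapply(1:50, function(s)
    mean(simulate_field(100, p$field_shape, p, seed = s)$is_responder),
    numeric(1))
  expect_lt(abs(mean(fracs) - 0.29), 0.03)
})

test_that("calcium series has flat baseline and genotype-scaled evoked peak", {
  tb <- default_timebase()
  p <- sim_params()
  f <- simulate_field(5, c(200, 200), p, seed = 3)
  cell <- f[which(f$is_responder)[1], ]
  s1 <- calcium_series(cell, tb, suppression = 0, genotype_amplitude = 1)
  s3 <- calcium_series(cell, tb, suppression = 0, genotype_amplitude = 3)
  expect_equal(s1[1:3], rep(cell$baseline_calcium, 3))
  expect_gt(which.max(s3), tb$n_pre)
  # evoked components scale exactly 3-fold
  expect_equal(max(s3) - cell$baseline_calcium,
               3 * (max(s1) - cell$baseline_calcium))
  # full suppression equals a non-responder
  s_blocked <- calcium_series(cell, tb, suppression = 1)
  nonresp <- cell; nonresp$peak_scale <- 0
  expect_equal(s_blocked, calcium_series(nonresp, tb))
  expect_equal(calcium_series(nonresp, tb), rep(cell$baseline_calcium, 13))
  bad <- cell; bad$rise_tau <- -1
  expect_error(calcium_series(bad, tb), "positive")
})

test_that("evoked peak decreases strictly with suppression at zero noise", {
  p <- ideal_params()
  peaks <- vapply(seq(0, 1, by = 0.25), function(s) {
    st <- simulate_well(p, seed = 11, suppression = s, n_cells = 10)
    seg <- segment_well(st)
    tr <- lapply(extract_traces(st, seg), normalize_trace, tb = st$timebase)
    mean(vapply(tr, peak_amplitude, numeric(1), tb = st$timebase))
  }, numeric(1))
  expect_true(all(diff(peaks) < 0))
})

test_that("sensor map is monotone and saturating", {
  sens <- sim_params()$sensor
  expect_gt(sensor_ratio(1, sens), sensor_ratio(0, sens))
  # near saturation doubling calcium raises the ratio by much less than 2x
  hi <- 50 * sens$k_half
  gain_hi <- sensor_ratio(2 * hi, sens) / sensor_ratio(hi, sens)
  expect_lt(gain_hi, 1.05)
  lo_gain <- (sensor_ratio(2 * 0.01, sens) - sens$r0) /
    (sensor_ratio(0.01, sens) - sens$r0)
  expect_equal(lo_gain, 2, tolerance = 1e-3)
})

test_that("render_stack produces the expected channel structure", {
  p <- ideal_params()
  tb <- default_timebase()
  # zero cells -> background-only frames
  empty <- simulate_field(0, p$field_shape, p, seed = 1)
  st0 <- render_stack(empty, matrix(0, 0, 13), tb, p)
  expect_equal(max(abs(st0$frames[1, "donor", , ] - p$background[["donor"]])), 0)
  # constant calcium, zero noise -> constant acceptor/donor ratio over time
  f <- simulate_field(3, p$field_shape, sim_params(responder_fraction = 1), seed = 4)
  calcium <- matrix(0.5, 3, 13)
  st <- render_stack(f, calcium, tb, p)
  mask <- st$truth$cell_labels == 1L
  ratios <- vapply(1:13, function(t) {
    mean(st$frames[t, "acceptor", , ][mask] - p$background[["acceptor"]]) /
      mean(st$frames[t, "donor", , ][mask] - p$background[["donor"]])
  }, numeric(1))
  expect_equal(max(ratios) - min(ratios), 0, tolerance = 1e-12)
  expect_equal(ratios[1], sensor_ratio(0.5, p$sensor), tolerance = 1e-12)
  expect_error(render_stack(f, matrix(0, 2, 13), tb, p), "matrix")
})

test_that("simulation is bit-identical for a fixed seed", {
  p <- fast_params()
  a <- simulate_well(p, seed = 9)
  b <- simulate_well(p, seed = 9)
  expect_identical(a$frames, b$frames)
  expect_identical(a$truth$cells, b$truth$cells)
})

test_that("simulate_plate applies role-dependent suppression", {
  layout <- plate_layout(character(0), n_dmso = 4L, n_untreated = 0L,
                         n_tp = 1L, n_cpa = 0L, n_tmb8 = 0L)
  layout <- layout[layout$role == "DMSO", ]
  p <- ideal_params()
  out <- simulate_plate(layout, p, seed = 1)
  expect_length(out$stacks, 4L)
  expect_true(all(out$truth$suppression == 0))
  expect_true(all(vapply(out$stacks, function(s) dim(s$frames)[1], numeric(1)) == 13))
  # TP ground truth: strong positive control
  expect_lte(true_normalized_response(p$control_suppression, p), 0.35)
  bad <- layout; bad$role[1] <- "mystery"
  expect_error(simulate_plate(bad, p, seed = 1), "unknown role")
})

test_that("full 384-well layouts validate and unknown roles are rejected", {
  l <- plate_layout(sprintf("C%02d", 1:85))
  expect_equal(nrow(l), 384L)
  expect_error(plate_layout(sprintf("C%02d", 1:95)), "384")
})
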
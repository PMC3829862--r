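make_well <- function(well_id, mean_peak, n_cells = 150L, n_resp = 140L,
                      valid = TRUE, bl_d = 400, bl_a = 400) {
  data.frame(well_id = well_id, n_cells = n_cells, n_responsive = n_resp,
             responsive_fraction = n_resp / n_cells,
             mean_peak_responsive = mean_peak, sd_peak_responsive = 0.05,
             mean_peak_all = mean_peak * n_resp / n_cells,
             baseline_donor = bl_d, baseline_acceptor = bl_a, valid = valid)
}

demo_layout <- function() {
  data.frame(well_id = sprintf("A%02d", 1:8),
             role = c("DMSO", "DMSO", "compound", "compound",
                      "compound", "compound", "TP", "TP"),
             compound_id = c(NA, NA, "X", "X", "Y", "Y", NA, NA),
             concentration_uM = c(NA, NA, 10, 10, 10, 10, NA, NA),
             replicate = c(1, 1, 1, 2, 1, 2, 1, 1))
}

test_that("DMSO normalization divides by the same-plate control mean", {
  wells <- rbind(make_well("A01", 1.0), make_well("A02", 1.0),
                 make_well("A03", 0.5), make_well("A04", 0.7),
                 make_well("A05", 0.9), make_well("A06", 1.1),
                 make_well("A07", 0.1), make_well("A08", 0.1))
  norm <- normalize_to_dmso(wells, demo_layout())
  expect_equal(norm$normalized_response[norm$well_id == "A03"], 0.5)
  expect_equal(mean(norm$normalized_response[norm$role == "DMSO"]), 1.0)
  # scale invariance
  wells2 <- wells; wells2$mean_peak_responsive <- wells$mean_peak_responsive * 3.7
  norm2 <- normalize_to_dmso(wells2, demo_layout())
  expect_equal(norm2$normalized_response, norm$normalized_response)
  # no valid DMSO well -> rejected
  wells3 <- wells; wells3$valid[1:2] <- FALSE
  expect_error(normalize_to_dmso(wells3, demo_layout()), "DMSO")
})

test_that("replicate aggregation uses mean and sample sd over valid wells", {
  wells <- rbind(make_well("A01", 1.0), make_well("A02", 1.0),
                 make_well("A03", 0.7), make_well("A04", 0.9),
                 make_well("A05", 0.8), make_well("A06", 0.8, valid = FALSE),
                 make_well("A07", 0.1), make_well("A08", 0.1))
  tab <- aggregate_replicates(normalize_to_dmso(wells, demo_layout()))
  x <- tab[tab$compound_id == "X", ]
  expect_equal(x$normalized_response_mean, 0.8)
  expect_equal(x$normalized_response_sd, stats::sd(c(0.7, 0.9)))
  y <- tab[tab$compound_id == "Y", ]
  expect_equal(y$n_valid, 1L)   # invalid replicate excluded and counted
  expect_equal(y$normalized_response_mean, 0.8)
  wells$valid[5:6] <- FALSE
  tab2 <- aggregate_replicates(normalize_to_dmso(wells, demo_layout()))
  expect_true(tab2$unmeasured[tab2$compound_id == "Y"])
})

test_that("hit calling is strict at the 0.9 boundary and artifact-aware", {
  tab <- data.frame(compound_id = c("A", "B", "C"),
                    n_replicates = 4L, n_valid = 4L,
                    normalized_response_mean = c(0.89, 0.90, 0.85),
                    normalized_response_sd = 0.01, unmeasured = FALSE,
                    autofluorescent = c(FALSE, FALSE, FALSE),
                    toxic = c(FALSE, FALSE, TRUE))
  out <- call_hits(tab)
  expect_equal(out$hit, c(TRUE, FALSE, FALSE))
})

test_that("artifact flags pick out bright-baseline and low-count compounds", {
  set.seed(42)
  layout <- data.frame(well_id = sprintf("A%02d", 1:10),
                       role = c(rep("DMSO", 4), rep("compound", 6)),
                       compound_id = c(rep(NA, 4), "ok", "ok", "glow", "glow",
                                       "kill", "kill"),
                       concentration_uM = c(rep(NA, 4), rep(10, 6)),
                       replicate = c(rep(1, 4), 1, 2, 1, 2, 1, 2))
  wells <- do.call(rbind, lapply(1:10, function(i) {
    bl <- 400 + stats::rnorm(1, 0, 2)
    w <- make_well(sprintf("A%02d", i), 1.0, bl_d = bl, bl_a = bl)
    w
  }))
  wells$baseline_donor[7:8] <- 700        # autofluorescent compound
  wells$n_cells[9:10] <- 20L              # toxic: 20 < 0.3 * 150
  norm <- normalize_to_dmso(wells, layout)
  tab <- flag_artifacts(norm, aggregate_replicates(norm))
  expect_equal(tab$autofluorescent[match(c("glow", "kill", "ok"), tab$compound_id)],
               c(TRUE, FALSE, FALSE))
  expect_equal(tab$toxic[match(c("glow", "kill", "ok"), tab$compound_id)],
               c(FALSE, TRUE, FALSE))
  # equal baselines -> no flag
  expect_false(any(tab$autofluorescent[tab$compound_id == "ok"]))
})

test_that("zprime reproduces hand-computed variants and properties", {
  # sigma 0 -> 1.0 for both variants
  q0 <- zprime(c(0.3, 0.3), c(1, 1))
  expect_equal(q0$zprime_canonical, 1)
  expect_equal(q0$zprime_as_printed, 1)
  # mu 0.3/1.0, sigma 0.02/0.03 (exact sample stats)
  tp <- c(0.28, 0.30, 0.32); dmso <- c(0.97, 1.00, 1.03)
  q <- zprime(tp, dmso)
  expect_equal(q$sigma_tp, 0.02)
  expect_equal(q$sigma_dmso, 0.03)
  expect_equal(q$zprime_canonical, 1 - 0.15 / 0.7)
  expect_equal(q$zprime_as_printed, 1 - 0.09 / 0.7)
  expect_lt(q$zprime_canonical, q$zprime_as_printed)
  # Z' <= 1 and decreases as spread grows
  q_wide <- zprime(c(0.2, 0.3, 0.4), dmso)
  expect_lt(q_wide$zprime_canonical, q$zprime_canonical)
  expect_lte(q$zprime_canonical, 1)
  expect_error(zprime(c(1, 1), c(1, 1)), "equal")
  expect_error(zprime(0.3, c(1, 1)), "2 wells")
})

test_that("responsive fraction report groups wells by condition", {
  wells <- rbind(make_well("A01", 0.2, n_resp = 29L, n_cells = 100L),
                 make_well("A02", 0.2, n_resp = 31L, n_cells = 100L),
                 make_well("A03", 0.6, n_resp = 96L, n_cells = 100L))
  rep_tab <- responsive_fraction_report(wells, c("WT", "WT", "FAD"))
  expect_equal(nrow(rep_tab), 2L)
  expect_equal(rep_tab$responsive_fraction_mean[rep_tab$condition == "WT"], 0.30)
  expect_equal(rep_tab$n_wells[rep_tab$condition == "FAD"], 1L)
})
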
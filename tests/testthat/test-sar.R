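test_that("Tanimoto dissimilarity matches hand arithmetic", {
  expect_equal(tanimoto_dissimilarity(c(1, 1, 0, 1), c(1, 1, 0, 1)), 0)
  expect_equal(tanimoto_dissimilarity(c(1, 1, 0, 0), c(0, 0, 1, 1)), 1)
  expect_equal(tanimoto_dissimilarity(c(1, 1, 0, 0), c(1, 0, 1, 0)), 2 / 3)
  expect_error(tanimoto_dissimilarity(c(1, 0), c(1, 0, 1)), "equal bit-length")
  expect_error(tanimoto_dissimilarity(c(0, 0), c(1, 0)), "set bit")
})

test_that("optisim_select handles degenerate geometries", {
  same <- matrix(rep(c(1, 0, 1, 0), 6), 6, 4, byrow = TRUE)
  rownames(same) <- sprintf("C%02d", 1:6)
  expect_length(optisim_select(same, 3, 0.2, seed = 1), 1L)
  two <- rbind(matrix(rep(c(1, 1, 0, 0), 3), 3, 4, byrow = TRUE),
               matrix(rep(c(0, 0, 1, 1), 3), 3, 4, byrow = TRUE))
  rownames(two) <- sprintf("C%02d", 1:6)
  sel <- optisim_select(two, 2, 0.5, seed = 2)
  expect_length(sel, 2L)
  expect_length(unique(sel <= 3), 2L)  # one from each group
  expect_length(optisim_select(matrix(numeric(0), 0, 4), 3, 0.3, seed = 1), 0L)
})

test_that("optisim_select equals the brute-force reference on all small instances", {
  for (s in 1:100) {
    set.seed(s + 10000)
    n <- sample(2:15, 1)
    fps <- matrix(as.integer(stats::runif(n * 16) < 0.4), n, 16)
    fps[rowSums(fps) == 0, 1] <- 1L
    rownames(fps) <- sprintf("C%02d", sample(n))
    k <- sample(1:4, 1); r <- stats::runif(1, 0.1, 0.7)
    expect_identical(optisim_select(fps, k, r, seed = s),
                     optisim_oracle(fps, k, r, seed = s))
  }
})

test_that("clustering partitions compounds and honors radii", {
  # one tight active group + distant inactives beyond the radius
  actives <- matrix(rep(c(1, 1, 1, 0, 0, 0, 0, 0), 5), 5, 8, byrow = TRUE)
  inactives <- matrix(rep(c(0, 0, 0, 0, 0, 1, 1, 1), 3), 3, 8, byrow = TRUE)
  fps <- rbind(actives, inactives)
  rownames(fps) <- sprintf("C%02d", 1:8)
  cl <- cluster_compounds(fps, active = c(rep(TRUE, 5), rep(FALSE, 3)),
                          radius_r = 0.4, seed = 1)
  expect_equal(nrow(cl$clusters), 1L)
  expect_equal(sort(cl$unclustered), sprintf("C%02d", 6:8))
  # partition: every compound appears exactly once
  expect_setequal(cl$membership$compound_id, rownames(fps))
  expect_equal(anyDuplicated(cl$membership$compound_id), 0L)
  # no active compounds -> empty clusters, everything pooled
  cl0 <- cluster_compounds(fps, active = rep(FALSE, 8), seed = 1)
  expect_equal(NROW(cl0$clusters), 0L)
  expect_length(cl0$unclustered, 8L)
})

test_that("cluster memberships are invariant to input permutation", {
  fps <- simulate_fingerprints(30, n_bits = 64, seed = 5)
  act <- attr(fps, "scaffold") <= 2
  part <- function(cl) {
    sp <- split(cl$membership$compound_id, cl$membership$cluster_id)
    lapply(sp[order(vapply(sp, min, character(1)))], sort)
  }
  cl1 <- cluster_compounds(fps, act, seed = 9)
  idx <- sample(nrow(fps))
  cl2 <- cluster_compounds(fps[idx, ], act[idx], seed = 9)
  expect_equal(unname(part(cl1)), unname(part(cl2)))
})

test_that("activity annotation follows the star and highlight rules", {
  tab <- data.frame(cluster_id = 1:4, representative = letters[1:4],
                    n_total = c(10L, 5L, 9L, 6L),
                    n_active = c(6L, 3L, 5L, 0L),
                    active_fraction = c(0.6, 0.6, 5 / 9, 0))
  ann <- annotate_clusters(tab)
  expect_equal(ann$star, c(TRUE, TRUE, TRUE, FALSE))
  # highlighted only when active count strictly exceeds four
  expect_equal(ann$highlighted, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(nrow(annotate_clusters(data.frame())), 0L)
})

test_that("cluster stats feed annotation consistently end to end", {
  fps <- simulate_fingerprints(40, n_scaffolds = 3, seed = 11)
  act <- stats::runif(40) < 0.5
  cl <- cluster_compounds(fps, act, seed = 3)
  ann <- annotate_clusters(cl)
  expect_equal(ann$star, ann$n_active / ann$n_total > 0.5)
  expect_equal(sum(cl$clusters$n_total) + length(cl$unclustered), 40L)
})
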
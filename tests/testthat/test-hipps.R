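test_that("maxent model reproduces an equilateral three-locus target", {
  R <- matrix(2, 3, 3)
  diag(R) <- 0
  m <- fit_maxent(R, tol = 0.01, max_iter = 100)
  expect_true(m$converged)
  ens <- sample_structures(m, 3000, seed = 2)
  dm <- distance_map_from_ensemble(ens)
  expect_lt(max(abs(dm$R[upper.tri(R)] / 2 - 1)), 0.05)
})

test_that("uniform scaling of the target scales the model distances", {
  set.seed(7)
  n <- 12
  walk <- apply(matrix(rnorm(n * 3), ncol = 3), 2, cumsum)
  R <- as.matrix(dist(walk)) * 0.8 + 0.2
  diag(R) <- 0
  R <- (R + t(R)) / 2
  m1 <- fit_maxent(R, tol = 0.02)
  m2 <- fit_maxent(3 * R, tol = 0.02)
  r1 <- ptadsuite:::.maxent_moments(m1$K)$r2
  r2 <- ptadsuite:::.maxent_moments(m2$K)$r2
  off <- upper.tri(R)
  expect_equal(sqrt(r2[off] / r1[off]), rep(3, sum(off)), tolerance = 0.05)
})

test_that("sampling is seed-deterministic, empty for n = 0, and matches the model", {
  R <- matrix(2, 4, 4) + diag(-2, 4)
  R[1, 4] <- R[4, 1] <- 3
  m <- fit_maxent(R, tol = 0.02)
  expect_equal(sample_structures(m, 0, seed = 1)$n_structures, 0)
  e1 <- sample_structures(m, 5, seed = 3)
  e2 <- sample_structures(m, 5, seed = 3)
  expect_identical(e1$coords, e2$coords)
  e3 <- sample_structures(m, 5, seed = 4)
  expect_false(identical(e1$coords, e3$coords))
  # ensemble mean distances approach the target
  big <- sample_structures(m, 4000, seed = 5)
  dm <- distance_map_from_ensemble(big)
  expect_lt(median(abs(dm$R[upper.tri(R)] / R[upper.tri(R)] - 1)), 0.05)
})

test_that("random valid targets are recovered within 5% median relative error", {
  # valid = realizable by the model class: draw a random coupling model,
  # read off its mean distances, and check the fit recovers them
  set.seed(19)
  for (rep in 1:3) {
    n <- sample(20:40, 1)
    K0 <- matrix(0, n, n)
    bb <- cbind(1:(n - 1), 2:n)
    K0[bb] <- runif(n - 1, 0.5, 3)
    K0[bb[, 2:1]] <- K0[bb]
    extra <- cbind(sample(n, 15, replace = TRUE),
                   sample(n, 15, replace = TRUE))
    extra <- extra[extra[, 1] != extra[, 2], , drop = FALSE]
    K0[extra] <- runif(nrow(extra), 0.05, 0.5)
    K0[extra[, 2:1]] <- K0[extra]
    r2 <- ptadsuite:::.maxent_moments(K0)$r2
    R <- sqrt(8 / (3 * pi)) * sqrt(r2)
    diag(R) <- 0
    m <- fit_maxent(R, tol = 0.02, max_iter = 200)
    expect_lte(m$median_rel_error, 0.05)
  }
})

test_that("strengthening block contacts shrinks its internal distances", {
  spec <- chromosome_spec(rep("A", 30))
  tads <- rbind(c(8L, 20L))
  lo <- make_block_contact_map(spec, tads, tad_enrichment = 2,
                               noise = "none")
  hi <- make_block_contact_map(spec, tads, tad_enrichment = 6,
                               noise = "none")
  dlo <- contacts_to_distances(lo)
  dhi <- contacts_to_distances(hi)
  inside <- dhi$R[9:18, 9:18][upper.tri(matrix(0, 10, 10))]
  inside_lo <- dlo$R[9:18, 9:18][upper.tri(matrix(0, 10, 10))]
  # scale anchor normalizes nearest neighbours; compare relative to an
  # untouched far pair
  expect_true(all(inside / dhi$R[1, 30] < inside_lo / dlo$R[1, 30]))
})

test_that("threshold calibration recovers the generating cutoff self-consistently", {
  spec <- chromosome_spec(rep("A", 25))
  cm <- make_block_contact_map(spec, rbind(c(6L, 18L)), tad_enrichment = 4,
                               noise = "none")
  h <- hipps_structures(cm, n_structures = 150, seed = 3, max_iter = 80,
                        calibrate = FALSE)
  ref <- contact_map_from_ensemble(h$ensemble, cutoff = 1.75)
  cal <- calibrate_contact_threshold(h$ensemble, ref)
  # within one grid step of the generating threshold
  step <- diff(cal$scan$threshold[1:2])
  expect_lt(abs(cal$threshold - 1.75), step + 1e-9)
  expect_gt(cal$objective, 0.99)
})
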
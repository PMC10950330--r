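test_that("boundary strengths equal the index-set enumeration oracle", {
  set.seed(13)
  for (rep in 1:10) {
    pts <- matrix(rnorm(30 * 3, sd = 2), ncol = 3)
    D <- as.matrix(dist(pts))
    got <- boundary_strengths(D)
    want <- oracle_strengths(D)
    expect_equal(got, want, tolerance = 1e-12)
  }
  # uniform off-diagonal distances -> all defined strengths are 1
  Du <- matrix(3, 25, 25)
  diag(Du) <- 0
  st <- boundary_strengths(Du)
  expect_true(all(st$start_strength[is.finite(st$start_strength)] == 1))
  expect_true(all(st$end_strength[is.finite(st$end_strength)] == 1))
})

test_that("two-cluster ensembles place the boundary probability at the junction", {
  be <- make_boundary_ensemble(60, 40, junction = 21, jitter = 1e-3,
                               seed = 9)
  bp <- boundary_probability(be)
  expect_equal(which.max(bp$mean_prob), 21)
  expect_gt(bp$mean_prob[21], 0.9)
  expect_true(all(bp$mean_prob[-21] < 0.1))
  expect_true(all(bp$mean_prob >= 0 & bp$mean_prob <= 1))
  expect_equal(bp$mean_prob, (bp$start_prob + bp$end_prob) / 2)
})

test_that("boundary probability is invariant under rigid-body transforms", {
  be <- make_boundary_ensemble(20, 40, junction = 17, jitter = 0.02,
                               seed = 4)
  bp1 <- boundary_probability(be)
  # rotate + translate every structure
  th <- 0.7
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  coords <- be$coords
  for (m in seq_len(dim(coords)[1]))
    coords[m, , ] <- matrix(coords[m, , ], ncol = 3) %*% Rz +
      matrix(c(5, -3, 2), 40, 3, byrow = TRUE)
  bp2 <- boundary_probability(ensemble(coords))
  expect_equal(bp1$mean_prob, bp2$mean_prob, tolerance = 1e-12)
  # and under structure reordering
  bp3 <- boundary_probability(ensemble(be$coords[20:1, , ]))
  expect_equal(bp1$mean_prob, bp3$mean_prob)
})

test_that("junction split across two loci gives ~0.5 probability at each", {
  be <- make_boundary_ensemble(800, 44, junction = c(15L, 29L), seed = 12,
                               jitter = 1e-3)
  bp <- boundary_probability(be)
  # binomial CI: 800 draws at p = 0.5 -> +-3.5 SE ~ 0.06
  expect_lt(abs(bp$mean_prob[15] - 0.5), 0.07)
  expect_lt(abs(bp$mean_prob[29] - 0.5), 0.07)
  expect_lt(max(bp$mean_prob[-c(15, 29)]), 0.1)
})

test_that("preferred boundaries are z-thresholded local maxima with monotone growth", {
  prof <- data.frame(mean_prob = c(rep(0.02, 9), 0.9, rep(0.02, 10)))
  expect_equal(preferred_boundaries(prof), 10L)
  flat <- data.frame(mean_prob = rep(0.3, 20))
  expect_length(preferred_boundaries(flat), 0)
  # lowering the threshold never removes a boundary
  set.seed(5)
  prof2 <- data.frame(mean_prob = pmax(0, cumsum(rnorm(50, 0, 0.05))))
  prev <- preferred_boundaries(prof2, z_threshold = 1.2)
  for (z in c(1.0, 0.7, 0.4, 0.1)) {
    cur <- preferred_boundaries(prof2, z_threshold = z)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("physical-boundary support requires peaks in both conditions", {
  # WT: junctions at 15 and 29; depleted keeps only 29
  wt <- make_boundary_ensemble(80, 44, junction = c(15L, 29L), seed = 3,
                               jitter = 1e-3)
  # per-structure junction alternates, so both peaks appear at ~0.5;
  # that is enough for preferred boundaries in WT
  dep <- make_boundary_ensemble(80, 44, junction = 29L, seed = 4,
                                jitter = 1e-3)
  pw <- boundary_probability(wt)
  pd <- boundary_probability(dep)
  tads <- tad_set(rbind(c(1L, 15L), c(15L, 29L), c(29L, 44L)), 44)
  pt <- match_ptads(tads, tads)
  ann <- ptad_boundary_support(pt, pw, pd)
  # [15,29) needs peaks at 15 and 29 in both: depleted lacks 15
  expect_equal(ann$boundary_support[2], "none")
  # identical profiles for both conditions: support equals WT preferred set
  ann2 <- ptad_boundary_support(pt, pw, pw)
  expect_equal(ann2$boundary_support[2], "physical-boundary")
})

test_that("DBSCAN matches the quadratic reference and the 2xD default", {
  expect_equal(formals(dbscan_clusters)$min_points, 6L)
  set.seed(21)
  for (rep in 1:8) {
    n <- sample(50:200, 1)
    k <- sample(1:4, 1)
    centers <- matrix(runif(k * 3, 0, 30), ncol = 3)
    pts <- do.call(rbind, lapply(seq_len(k), function(c)
      matrix(rnorm(3 * ceiling(n / k), sd = 0.8), ncol = 3) +
        matrix(centers[c, ], ceiling(n / k), 3, byrow = TRUE)))
    lab_got <- ptadsuite:::.dbscan_core(pts, eps = 1.5, min_points = 6)
    lab_ref <- reference_dbscan(pts, eps = 1.5, min_points = 6)
    expect_true(same_partition(lab_got, lab_ref))
  }
})

test_that("cluster statistics count A and B clusters separately", {
  set.seed(6)
  xyz <- rbind(matrix(rnorm(30, 0, 0.3), ncol = 3),   # 10 A
               matrix(rnorm(30, 10, 0.3), ncol = 3),  # 10 A far away
               matrix(rnorm(18, 5, 0.3), ncol = 3))   # 6 B
  types <- c(rep("A", 20), rep("B", 6))
  cl <- dbscan_clusters(xyz, types, eps = 1.5)
  expect_equal(unname(cl$n_clusters["A"]), 2L)
  expect_equal(unname(cl$n_clusters["B"]), 1L)
  expect_equal(cl$size_fractions$A, c(0.5, 0.5))
  expect_equal(cl$size_fractions$B, 1)
  # fewer than min_points of a type: all noise
  cl2 <- dbscan_clusters(xyz[1:25, ], types[1:25], eps = 1.5)
  expect_equal(unname(cl2$n_clusters["B"]), 0L)
})

test_that("k-distance elbow sits between the two scales of a two-scale set", {
  set.seed(10)
  # tight core (spacing ~0.2) plus far-flung sparse points (spacing ~5)
  pts <- rbind(matrix(rnorm(60, 0, 0.2), ncol = 3),
               matrix(runif(30, 10, 30), ncol = 3))
  ke <- kdistance_elbow(pts, k = 6)
  expect_true(all(diff(ke$kdist) >= -1e-12))  # non-decreasing
  expect_gt(ke$eps, 0.1)
  expect_lt(ke$eps, 25)
  expect_warning(kdistance_elbow(matrix(0, 10, 3)), "degenerate")
  expect_error(kdistance_elbow(matrix(rnorm(9), 3, 3), k = 6), "k \\+ 1")
})
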
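test_that("contact maps from ensembles equal the brute-force double loop", {
  set.seed(11)
  coords <- array(rnorm(50 * 20 * 3, sd = 2), dim = c(50, 20, 3))
  ens <- ensemble(coords)
  cm <- contact_map_from_ensemble(ens, cutoff = 1.75)
  # independent O(M N^2) oracle
  ref <- matrix(0, 20, 20)
  for (m in 1:50) for (i in 1:19) for (j in (i + 1):20) {
    r <- sqrt(sum((coords[m, i, ] - coords[m, j, ])^2))
    if (r < 1.75) {
      ref[i, j] <- ref[i, j] + 1
      ref[j, i] <- ref[j, i] + 1
    }
  }
  diag(ref) <- 50
  expect_equal(cm$C, ref)
  expect_true(all(cm$C >= 0 & cm$C <= 50))

  # two-locus sanity: in contact iff r < cutoff
  one <- ensemble(array(c(0, 1.0, 0, 0, 0, 0), dim = c(1, 2, 3)))
  expect_equal(contact_map_from_ensemble(one)$C[1, 2], 1)
  far <- ensemble(array(c(0, 2.0, 0, 0, 0, 0), dim = c(1, 2, 3)))
  expect_equal(contact_map_from_ensemble(far)$C[1, 2], 0)
  expect_error(contact_map_from_ensemble(one, cutoff = 0), "cutoff")
})

test_that("z-score transform standardizes each diagonal and kills Toeplitz structure", {
  # Toeplitz matrix: entries depend only on separation -> all-zero Z
  n <- 12
  Tm <- outer(1:n, 1:n, function(i, j) 10 / (1 + abs(i - j)))
  expect_true(all(zscore_transform(Tm, log_transform = TRUE) == 0))

  set.seed(3)
  C <- matrix(rpois(15 * 15, 40), 15, 15)
  C <- C + t(C)
  Z <- zscore_transform(C)
  for (s in 1:10) {
    i <- 1:(15 - s)
    v <- Z[cbind(i, i + s)]
    if (length(v) >= 2 && sd(v) > 0) {
      expect_equal(mean(v), 0, tolerance = 1e-10)
      expect_equal(sd(v), 1, tolerance = 1e-10)
    }
  }
  # hand-computed 5x5 stratified standardization of the first diagonal
  C5 <- matrix(0, 5, 5)
  C5[cbind(1:4, 2:5)] <- c(10, 20, 30, 40)
  C5 <- C5 + t(C5)
  diag(C5) <- 50
  Z5 <- zscore_transform(C5)
  lv <- log1p(c(10, 20, 30, 40))
  expect_equal(Z5[cbind(1:4, 2:5)], (lv - mean(lv)) / sd(lv),
               tolerance = 1e-12)
  # idempotence in distribution: re-standardizing changes moments < 1e-10
  Z2 <- zscore_transform(Z, log_transform = FALSE)
  for (s in 1:10) {
    i <- 1:(15 - s)
    v <- Z2[cbind(i, i + s)]
    if (length(v) >= 2 && sd(v) > 0) expect_equal(mean(v), 0, tolerance = 1e-10)
  }
})

test_that("pearson map reproduces the textbook correlation and bounds", {
  Z <- rbind(c(1, 2, 3, 4), c(2, 4, 6, 8), c(-1, -2, -3, -4),
             c(4, 3, 5, 1))
  rho <- pearson_map(Z)
  expect_equal(rho[1, 2], 1)
  expect_equal(rho[1, 3], -1)
  expect_equal(rho[1, 4], cor(Z[1, ], Z[4, ]), tolerance = 1e-12)
  expect_true(all(abs(rho[is.finite(rho)]) <= 1 + 1e-12))
  # zero-variance profile is masked
  Zv <- rbind(c(0, 0, 0), c(1, 2, 3), c(3, 1, 2))
  expect_true(all(is.na(pearson_map(Zv)[1, ])))
})

test_that("KL divergence matches direct evaluation, is asymmetric and non-negative", {
  # two-bin analytic case with pseudo-count folded in
  p <- c(rep(-0.5, 50), rep(0.5, 50))
  q <- c(rep(-0.5, 90), rep(0.5, 10))
  got <- kl_divergence(p, q, n_bins = 2, pseudo_count = 1)
  ph <- c(51, 51) / 102
  qh <- c(91, 11) / 102
  expect_equal(got, sum(ph * log(ph / qh)), tolerance = 1e-12)
  expect_equal(kl_divergence(p, p), 0)
  expect_false(isTRUE(all.equal(kl_divergence(p, q), kl_divergence(q, p))))
  # non-negativity over random distribution pairs
  set.seed(4)
  for (i in 1:200) {
    a <- runif(60, -1, 1)
    b <- runif(60, -1, 1)
    expect_gte(kl_divergence(a, b), 0)
  }
})

test_that("PC1 of a two-block checkerboard alternates with the blocks", {
  blocks <- rep(c("A", "B"), each = 10)
  rho <- outer(blocks, blocks, function(a, b) ifelse(a == b, 1, -1))
  p <- pc1_compartments(rho, states = blocks)
  expect_true(all(p$pc1[blocks == "A"] > 0))
  expect_true(all(p$pc1[blocks == "B"] < 0))
  # flipping the supplied track flips orientation only
  p2 <- pc1_compartments(rho, states = rev(blocks))
  expect_equal(abs(p2$pc1), abs(p$pc1), tolerance = 1e-10)
  expect_error(pc1_compartments(matrix(1, 5, 5)), "degenerate")
})

test_that("contact/distance power-law conversion is a monotone round trip", {
  spec <- chromosome_spec(rep("A", 15))
  cm <- make_block_contact_map(spec, noise = "none")
  dm <- contacts_to_distances(cm, exponent = 4.1)
  # contact ratio 16 -> distance ratio 16^(1/4.1)
  i <- cbind(c(1, 1), c(2, 5))
  pr <- cm$C[1, 2] / cm$C[1, 5]
  expect_equal(dm$R[1, 5] / dm$R[1, 2], pr^(1 / 4.1), tolerance = 1e-10)
  # nearest-neighbour scale anchor
  expect_equal(mean(dm$R[cbind(1:14, 2:15)]), 1, tolerance = 1e-12)
  # round trip up to scale: correlation of logs = 1
  cm2 <- distances_to_contacts(dm, exponent = 4.1)
  u <- upper.tri(cm$C)
  expect_equal(cor(log(cm2$C[u]), log(cm$C[u])), 1, tolerance = 1e-10)
  r1 <- log(cm2$C[u]) - log(cm$C[u])
  expect_lt(diff(range(r1)), 1e-10)  # constant offset only
  expect_error(contacts_to_distances(cm, exponent = -1), "exponent")
})

test_that("Ward linkage matrix is an ultrametric that separates blocks", {
  set.seed(8)
  pts <- rbind(matrix(rnorm(45, 0, 0.3), ncol = 3),
               matrix(rnorm(45, 8, 0.3), ncol = 3))
  D <- as.matrix(dist(pts))
  wl <- ward_linkage_matrix(D)
  W <- wl$W
  expect_equal(compare_wlm(wl, wl), 1)
  expect_true(max(W[1:15, 1:15]) < min(W[1:15, 16:30]))
  # ultrametric inequality on sampled triples
  for (k in 1:200) {
    ijk <- sample(30, 3)
    expect_gte(max(W[ijk[1], ijk[2]], W[ijk[2], ijk[3]]) + 1e-9,
               W[ijk[1], ijk[3]])
  }
  # identical points merge at height zero
  same <- matrix(1, 6, 6) - diag(6)
  expect_true(all(ward_linkage_matrix(same * 0)$W == 0))
})
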
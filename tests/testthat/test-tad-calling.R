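test_that("binsignal is the mean over the w-window rectangle, truncated at ends", {
  n <- 30
  set.seed(2)
  C <- matrix(rpois(n * n, 30), n, n)
  C <- (C + t(C)) / 2
  bs <- binsignal(C, w = 4)
  # brute-force window means
  for (i in c(1, 3, 12, 29)) {
    up <- max(1, i - 3):i
    dn <- (i + 1):min(n, i + 4)
    expect_equal(bs[i], mean(C[up, dn]), tolerance = 1e-12)
  }
  expect_true(is.na(bs[n]))
  # uniform matrix -> constant binSignal
  expect_equal(diff(range(binsignal(matrix(5, 20, 20), 5)[1:19])), 0)
  # wider-than-chromosome window still defined
  expect_true(all(is.finite(binsignal(matrix(5, 6, 6), 20)[1:5])))
})

test_that("caller recovers implanted boundaries and returns none on uniform maps", {
  spec <- chromosome_spec(rep("A", 100))
  tads <- rbind(c(1, 41), c(41, 71), c(71, 101))
  cm <- make_block_contact_map(spec, tads, tad_enrichment = 3,
                               noise = "none")
  ts <- call_tads(cm, w = 5)
  expect_setequal(setdiff(unique(c(ts$intervals)), c(1, 101)), c(41, 71))
  # uniform matrix: no boundaries
  expect_equal(nrow(call_tads(matrix(7, 50, 50))$intervals), 0)
  # all-missing matrix: empty set
  expect_equal(nrow(call_tads(matrix(0, 30, 30))$intervals), 0)
})

test_that("larger w yields no more boundaries than smaller w", {
  spec <- chromosome_spec(rep("A", 120))
  set.seed(31)
  layout <- random_tad_layout(120)
  cm <- make_block_contact_map(spec, layout, tad_enrichment = 3,
                               noise = "poisson", seed = 5)
  n5 <- nrow(call_tads(cm, w = 5)$intervals)
  n20 <- nrow(call_tads(cm, w = 20)$intervals)
  expect_lte(n20, n5)
})

test_that("permutation-null maps yield almost no boundaries (specificity)", {
  spec <- chromosome_spec(rep("A", 200))
  set.seed(17)
  n_structured <- 0
  n_null <- 0
  for (rep in 1:4) {
    layout <- random_tad_layout(200)
    cm <- make_block_contact_map(spec, layout, tad_enrichment = 3,
                                 noise = "poisson", seed = 60 + rep)
    bs <- setdiff(unique(c(call_tads(cm)$intervals)), c(1, 201))
    n_structured <- n_structured + length(bs)
    nullC <- shuffle_within_diagonals(cm$C)
    bn <- setdiff(unique(c(call_tads(contact_map(nullC))$intervals)),
                  c(1, 201))
    n_null <- n_null + length(bn)
  }
  expect_lte(n_null, 0.05 * n_structured)
})

test_that("missing-bin filter drops boundaries with > 1 missing bin within 250 kb", {
  spec <- chromosome_spec(rep("A", 100))
  tads <- rbind(c(1, 41), c(41, 71), c(71, 101))
  # two missing bins within 5 bins of boundary 41; one near boundary 71
  cm <- make_block_contact_map(spec, tads, tad_enrichment = 3,
                               noise = "none", missing_bins = c(38L, 43L, 69L))
  ts <- tad_set(rbind(c(1L, 41L), c(41L, 71L), c(71L, 101L)), 100)
  filt <- missing_bin_filter(ts, cm)
  # domains touching boundary 41 (two missing bins nearby) are removed;
  # boundary 71 has exactly one missing bin -> kept
  expect_false(any(filt$intervals[, 2] == 41))
  expect_false(any(filt$intervals[, 1] == 41))
  expect_true(any(filt$intervals[, 1] == 71))
  # no missing bins -> identity
  cm0 <- make_block_contact_map(spec, tads, noise = "none")
  expect_equal(missing_bin_filter(ts, cm0)$intervals, ts$intervals)
})

test_that("P-TAD matching follows the boundary window and reciprocal overlap rule", {
  wt <- tad_set(rbind(c(1L, 11L), c(11L, 21L), c(21L, 41L)), 40, "WT")
  # identical sets: everything preserved with zero offsets
  m <- match_ptads(wt, wt)
  expect_true(all(m$preserved))
  expect_true(all(m$start_offset == 0 & m$end_offset == 0))
  # one boundary shifted by 1 bin on a 10-bin TAD (overlap 0.9): preserved
  dep <- tad_set(rbind(c(1L, 11L), c(12L, 21L), c(21L, 41L)), 40, "dep")
  m2 <- match_ptads(wt, dep)
  expect_true(m2$preserved[2])
  expect_equal(m2$overlap[2], 0.9)
  # boundary shifted by 3 bins: not preserved
  dep3 <- tad_set(rbind(c(1L, 11L), c(14L, 21L), c(21L, 41L)), 40, "dep")
  expect_false(match_ptads(wt, dep3)$preserved[2])
  # 1-bin shift on a short TAD can fail the 80% overlap despite the window
  wt_s <- tad_set(rbind(c(1L, 5L)), 10, "WT")
  dep_s <- tad_set(rbind(c(2L, 5L)), 10, "dep")
  expect_false(match_ptads(wt_s, dep_s)$preserved[1])  # overlap 0.75
})

test_that("matching agrees with the all-pairs brute-force oracle on random sets", {
  set.seed(23)
  for (rep in 1:300) {
    n <- 60
    wi <- random_tad_layout(n, 3, 12)
    di <- random_tad_layout(n, 3, 12)
    wt <- tad_set(wi, n, "WT")
    dep <- tad_set(di, n, "dep")
    got <- match_ptads(wt, dep)$preserved
    want <- brute_force_match(wi, di)
    expect_identical(got, want)
  }
})

test_that("switch detection excludes single-locus runs (filter I)", {
  expect_equal(detect_switches(c(rep("A", 5), rep("B", 5))), 6L)
  expect_length(detect_switches(c("A", "A", "A", "B", "A", "A", "A")), 0)
  expect_equal(detect_switches(rep(c("A", "A", "B", "B"), 2)),
               c(3L, 5L, 7L))
  expect_length(detect_switches(rep("A", 10)), 0)
})

test_that("switch classifier applies proximity and purity filters (II-III)", {
  res <- 50000
  # 20-bin track: A x10, B x10; switch at bin 11
  states <- rep(c("A", "B"), each = 10)
  sw <- detect_switches(states)
  wt <- tad_set(rbind(c(1L, 11L), c(11L, 21L)), 20, "WT")
  ptads <- match_ptads(wt, wt)  # both preserved
  ann <- classify_switch_ptads(ptads, sw, states, res)
  expect_true(all(ann$switch_status == "switch-preserved"))
  expect_true(all(ann$switch_boundary == 11L))

  # switch 150 kb away from any boundary: not associated
  wt2 <- tad_set(rbind(c(1L, 8L), c(14L, 21L)), 20, "WT")
  ann2 <- classify_switch_ptads(match_ptads(wt2, wt2), sw, states, res)
  expect_true(all(ann2$switch_status == "no-switch"))

  # purity filter: switch at the boundary itself (bin 11), right TAD
  # 70% pure (passes the >= threshold) vs 60% pure (filtered out)
  states3 <- c(rep("A", 10), rep("B", 7), rep("A", 3))
  sw3 <- detect_switches(states3)
  expect_true(11L %in% sw3)
  ann3 <- classify_switch_ptads(match_ptads(wt, wt), sw3, states3, res)
  expect_true(all(ann3$switch_status == "switch-preserved"))
  states4 <- c(rep("A", 10), rep("B", 6), rep("A", 4))
  sw4 <- detect_switches(states4)
  ann4 <- classify_switch_ptads(match_ptads(wt, wt), sw4, states4, res)
  # the right-hand TAD [11,21) is only 60% one state: both records that
  # rely on boundary 11 are filtered
  expect_true(all(ann4$switch_status == "filtered"))
  # non-preserved records are labelled as such
  dep0 <- tad_set(matrix(integer(), ncol = 2), 20, "dep")
  ann5 <- classify_switch_ptads(match_ptads(wt, dep0), sw, states, res)
  expect_true(all(ann5$switch_status == "not-preserved"))
})

test_that("end-to-end: only switch-bounded TADs stay after simulated loop removal", {
  # A[1,31) B[31,61) A[61,101); loop TADs [31,61) (switch-bounded) and
  # [71,91) (inside the homogeneous A block)
  states <- make_epigenetic_sequence(c(30, 30, 40), "A")$states
  spec <- chromosome_spec(states)
  wt_tads <- rbind(c(31L, 61L), c(71L, 91L))
  cm_wt <- make_block_contact_map(spec, wt_tads, tad_enrichment = 3,
                                  compartment_enrichment = 1.5,
                                  noise = "poisson", seed = 71)
  # loop removal: TAD enrichment gone, compartments stay
  cm_dep <- make_block_contact_map(spec, matrix(integer(), ncol = 2),
                                   tad_enrichment = 1,
                                   compartment_enrichment = 1.5,
                                   noise = "poisson", seed = 72)
  t_wt <- call_tads(cm_wt, condition = "WT")
  t_dep <- call_tads(cm_dep, condition = "dep")
  pt <- match_ptads(t_wt, t_dep)
  ann <- classify_switch_ptads(pt, detect_switches(states), states)
  sp <- ann[ann$switch_status == "switch-preserved", ]
  # every preserved switch-associated TAD has a boundary within 1 bin of
  # an implanted switch (31 or 61), and the B block itself is among them
  expect_true(nrow(sp) >= 1)
  near_switch <- function(b) min(abs(b - c(31L, 61L))) <= 1L
  expect_true(all(vapply(seq_len(nrow(sp)), function(k)
    near_switch(sp$wt_start[k]) || near_switch(sp$wt_end[k]), logical(1))))
  expect_true(any(abs(sp$wt_start - 31L) <= 1 & abs(sp$wt_end - 61L) <= 1))
  # the loop-only TAD [71, 91) is not preserved
  loop_row <- ann[ann$wt_start == 71L & ann$wt_end == 91L, ]
  if (nrow(loop_row)) expect_false(any(loop_row$preserved))
})
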
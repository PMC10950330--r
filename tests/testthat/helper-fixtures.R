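# Shared fixtures and independent oracles used across the test files.
# Everything is generated in code; no stored data.

# random tiling of [1, n+1) into domains with sizes in [min_size, max_size]
random_tad_layout <- function(n, min_size = 8L, max_size = 30L) {
  edges <- 1L
  while (tail(edges, 1) < n + 1L - max_size) {
    step <- sample(min_size:max_size, 1L)
    edges <- c(edges, tail(edges, 1) + step)
  }
  edges <- c(edges, n + 1L)
  cbind(edges[-length(edges)], edges[-1])
}

# shuffle a contact matrix within each diagonal (permutation null that
# preserves the distance-decay profile but destroys positional structure)
shuffle_within_diagonals <- function(C) {
  n <- nrow(C)
  S <- matrix(0, n, n)
  for (s in 1:(n - 1)) {
    i <- 1:(n - s)
    v <- C[cbind(i, i + s)]
    v <- v[sample.int(length(v))]
    S[cbind(i, i + s)] <- v
    S[cbind(i + s, i)] <- v
  }
  diag(S) <- diag(C)
  S
}

# brute-force O(N^2) copolymer energy: plain triple loop over the three
# energy terms, independent of the vectorized implementation
brute_force_energy <- function(xyz, spec, ff, exclude_bonded_lj = TRUE) {
  n <- nrow(xyz)
  e <- 0
  for (i in 1:(n - 1)) {
    r <- sqrt(sum((xyz[i, ] - xyz[i + 1, ])^2))
    e <- e - 0.5 * ff$k_fene * ff$r0_fene^2 * log(1 - (r / ff$r0_fene)^2)
  }
  gap_min <- if (exclude_bonded_lj) 2L else 1L
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (j - i < gap_min) next
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    eps <- if (spec$states[i] == spec$states[j]) {
      if (spec$states[i] == "A") ff$eps_aa else ff$eps_bb
    } else ff$eps_ab
    e <- e + 4 * eps * ((ff$sigma / r)^12 - (ff$sigma / r)^6)
  }
  if (spec$pl > 0 && nrow(spec$loop_anchors)) {
    for (a in seq_len(nrow(spec$loop_anchors))) {
      p <- spec$loop_anchors[a, 1]; q <- spec$loop_anchors[a, 2]
      r <- sqrt(sum((xyz[p, ] - xyz[q, ])^2))
      e <- e + ff$k_h * (r - ff$r0_h)^2
    }
  }
  e
}

# all-pairs brute-force P-TAD matcher: same rule as match_ptads but written
# as an explicit double loop with greedy assignment by descending overlap
brute_force_match <- function(wi, di, window_bins = 1L, min_overlap = 0.8) {
  nw <- nrow(wi)
  nd <- nrow(di)
  preserved <- rep(FALSE, nw)
  if (!nw || !nd) return(preserved)
  cand <- list()
  for (q in seq_len(nw)) for (s in seq_len(nd)) {
    inter <- min(wi[q, 2], di[s, 2]) - max(wi[q, 1], di[s, 1])
    if (inter <= 0) next
    fw <- inter / (wi[q, 2] - wi[q, 1])
    fd <- inter / (di[s, 2] - di[s, 1])
    frac <- min(fw, fd)
    if (abs(di[s, 1] - wi[q, 1]) <= window_bins &&
        abs(di[s, 2] - wi[q, 2]) <= window_bins && frac >= min_overlap)
      cand[[length(cand) + 1L]] <- c(q, s, frac)
  }
  if (!length(cand)) return(preserved)
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand[, 3], cand[, 1], cand[, 2]), , drop = FALSE]
  used_d <- rep(FALSE, nd)
  for (r in seq_len(nrow(cand))) {
    q <- cand[r, 1]; s <- cand[r, 2]
    if (preserved[q] || used_d[s]) next
    preserved[q] <- TRUE
    used_d[s] <- TRUE
  }
  preserved
}

# boundary-strength oracle: medians over explicitly enumerated index sets
oracle_strengths <- function(D, n_cols = 3L, col_depth = 6L) {
  n <- nrow(D)
  ss <- rep(NA_real_, n)
  es <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lc <- (i - n_cols):(i - 1)
    rc <- i:(i + n_cols - 1)
    if (lc[1] >= 1 && max(rc) + col_depth <= n) {
      L <- median(unlist(lapply(lc, function(c) D[(c + 1):(c + col_depth), c])))
      R <- median(unlist(lapply(rc, function(c) D[(c + 1):(c + col_depth), c])))
      if (R > 0) ss[i] <- L / R
    }
    if (lc[1] - col_depth >= 1 && max(rc) <= n) {
      Tm <- median(unlist(lapply(lc, function(c) D[(c - col_depth):(c - 1), c])))
      B <- median(unlist(lapply(rc, function(c) D[(c - col_depth):(c - 1), c])))
      if (Tm > 0) es[i] <- B / Tm
    }
  }
  data.frame(start_strength = ss, end_strength = es)
}

# quadratic-time DBSCAN reference: core points by explicit region query,
# clusters as connected components of the core-core graph plus reachable
# border points (label values may differ; compare partitions)
reference_dbscan <- function(xyz, eps, min_points) {
  n <- nrow(xyz)
  if (!n) return(integer())
  D <- as.matrix(dist(xyz))
  nb <- D <= eps
  core <- rowSums(nb) >= min_points
  lab <- rep(0L, n)
  cl <- 0L
  # components over core points
  for (i in which(core)) {
    if (lab[i] != 0L) next
    cl <- cl + 1L
    comp <- i
    repeat {
      grow <- which(core & lab == 0L &
                      apply(nb[, comp, drop = FALSE], 1, any))
      grow <- setdiff(grow, comp)
      if (!length(grow)) break
      comp <- c(comp, grow)
    }
    lab[comp] <- cl
  }
  # border points: attach to the cluster of some core neighbour
  for (i in which(!core & lab == 0L)) {
    cn <- which(core & nb[i, ])
    if (length(cn)) lab[i] <- lab[cn[1]]
  }
  lab
}

# compare two clustering labelings up to label permutation (noise = 0
# must coincide exactly); border points may be reachable from two
# clusters, in which case either assignment is valid -- `loose` drops them
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!all((a == 0) == (b == 0))) return(FALSE)
  for (l in setdiff(unique(a), 0L)) {
    m <- b[a == l]
    if (length(unique(m)) != 1) return(FALSE)
  }
  for (l in setdiff(unique(b), 0L)) {
    m <- a[b == l]
    if (length(unique(m)) != 1) return(FALSE)
  }
  TRUE
}
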
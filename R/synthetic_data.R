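## Synthetic chromosomes with known ground truth.
##
## These generators emulate the statistical structure the analysis stages
## assume real data to have: block A/B epigenetic tracks with switches,
## loop-anchored TADs, power-law contact decay P(s) ~ s^-gamma, compartment
## checkerboards, and structure ensembles with sharp spatial junctions.
## Every generator is seed-deterministic.

#' Block A/B epigenetic sequence with known switch positions
#'
#' Lays down alternating A/B blocks of the given lengths, starting from
#' `first_state`. A "switch" is the first bin of each new block; single-locus
#' filtering is *not* applied here (that is the job of [detect_switches()]),
#' so the returned `switch_positions` are simply the block junctions.
#'
#' @param block_lengths integer vector of block lengths (bins), all >= 1.
#' @param first_state "A" or "B".
#' @return list with `states` (character vector) and `switch_positions`
#'   (1-based bin index of the first bin of each block after the first).
#' @export
make_epigenetic_sequence <- function(block_lengths, first_state = "A") {
  block_lengths <- as.integer(block_lengths)
  if (!length(block_lengths)) stop("block_lengths must be non-empty")
  if (any(block_lengths < 1L)) stop("all block lengths must be >= 1")
  first_state <- match.arg(first_state, c("A", "B"))
  lab <- rep(c(first_state, setdiff(c("A", "B"), first_state)),
             length.out = length(block_lengths))
  states <- rep(lab, times = block_lengths)
  sw <- if (length(block_lengths) > 1)
    1L + cumsum(block_lengths)[-length(block_lengths)] else integer()
  list(states = states, switch_positions = sw)
}

#' Random block layout drawn from a geometric-ish block-length distribution
#'
#' Convenience wrapper: draws block lengths uniformly in
#' `[min_block, max_block]` until at least `n_loci` bins are covered, then
#' trims the last block. Reproducible under the same seed.
#'
#' @param n_loci total bins.
#' @param min_block,max_block block length bounds (bins).
#' @param seed integer seed.
#' @inheritParams make_epigenetic_sequence
#' @export
random_epigenetic_sequence <- function(n_loci, min_block = 4L,
                                       max_block = 20L,
                                       first_state = "A", seed = 1L) {
  stopifnot(n_loci >= 1, min_block >= 1, max_block >= min_block)
  set.seed(seed)
  lens <- integer()
  while (sum(lens) < n_loci)
    lens <- c(lens, sample.int(max_block - min_block + 1L, 1L) +
                min_block - 1L)
  excess <- sum(lens) - n_loci
  lens[length(lens)] <- lens[length(lens)] - excess
  lens <- lens[lens > 0L]
  make_epigenetic_sequence(lens, first_state)
}

#' Analytic block contact map with implanted TADs and compartments
#'
#' Builds the expected contact matrix
#' `E_ij = p0 * |i-j|^-decay_exponent` (for i != j), multiplies entries
#' inside each implanted TAD by `tad_enrichment` and same-compartment pairs
#' by `compartment_enrichment`, then (optionally) replaces each upper-triangle
#' entry by an independent Poisson draw with that mean. The diagonal is set
#' to `p0 * diag_factor` so that rows never sum to zero unless a bin is
#' deliberately knocked out via `missing_bins`.
#'
#' @param spec a [chromosome_spec()] supplying states and resolution.
#' @param tads integer matrix (start, end) of half-open bin intervals to
#'   enrich, possibly 0 rows.
#' @param p0 contact scale at s = 1.
#' @param decay_exponent power-law exponent gamma > 0 of P(s) ~ s^-gamma.
#' @param tad_enrichment fold enrichment (>= 1) within TADs.
#' @param compartment_enrichment fold enrichment (>= 1) for same-state pairs.
#' @param noise "none" for the analytic map, "poisson" for count noise.
#' @param missing_bins bins whose row+column are zeroed (missing-bin
#'   synthesis; the operational definition of a missing bin is a row whose
#'   contact frequencies sum to zero).
#' @param seed integer seed (used only when `noise = "poisson"`).
#' @param diag_factor diagonal value as a multiple of `p0`.
#' @return a [contact_map()].
#' @export
make_block_contact_map <- function(spec, tads = matrix(integer(), ncol = 2),
                                   p0 = 100, decay_exponent = 1.0,
                                   tad_enrichment = 3,
                                   compartment_enrichment = 1,
                                   noise = c("none", "poisson"),
                                   missing_bins = integer(), seed = 1L,
                                   diag_factor = 2) {
  noise <- match.arg(noise)
  if (decay_exponent <= 0) stop("decay_exponent must be > 0")
  if (tad_enrichment < 1 || compartment_enrichment < 1)
    stop("enrichments must be >= 1")
  n <- spec$n_loci
  tads <- matrix(as.integer(tads), ncol = 2)
  if (nrow(tads) && (any(tads[, 1] < 1L) || any(tads[, 2] > n + 1L) ||
                     any(tads[, 1] >= tads[, 2])))
    stop("TAD intervals outside matrix")
  s <- abs(outer(seq_len(n), seq_len(n), "-"))
  E <- p0 * ifelse(s == 0, diag_factor, s^(-decay_exponent))
  if (compartment_enrichment > 1) {
    same <- outer(spec$states, spec$states, "==")
    E[same & s > 0] <- E[same & s > 0] * compartment_enrichment
  }
  if (tad_enrichment > 1 && nrow(tads)) {
    for (k in seq_len(nrow(tads))) {
      idx <- tads[k, 1]:(tads[k, 2] - 1L)
      off <- s[idx, idx] > 0
      E[idx, idx][off] <- E[idx, idx][off] * tad_enrichment
    }
  }
  if (noise == "poisson") {
    set.seed(seed)
    up <- upper.tri(E)
    E[up] <- rpois(sum(up), E[up])
    E[lower.tri(E)] <- t(E)[lower.tri(E)]
  }
  if (length(missing_bins)) {
    E[missing_bins, ] <- 0
    E[, missing_bins] <- 0
  }
  contact_map(E, resolution_bp = spec$resolution_bp)
}

#' Two-cluster structure ensemble with a sharp spatial junction
#'
#' Each structure consists of two spatially compact clusters of loci,
#' `[1, junction)` and `[junction, n_loci]`, whose centroids sit `separation`
#' apart along x, with isotropic Gaussian jitter of sd `jitter` on every
#' locus. Within each cluster loci sit on a deterministic compact backbone
#' (spacing `intra_scale`), so intra-cluster distances stay well below
#' `separation` and the jitter -> 0 limit is exactly reproducible. If
#' `junction` is a vector, each structure draws its junction uniformly from
#' it (used to emulate cell-to-cell boundary variability).
#'
#' @param n_structures number of structures.
#' @param n_loci loci per structure.
#' @param junction junction locus (first locus of the second cluster),
#'   scalar or vector of candidates; all in (1, n_loci].
#' @param separation centroid separation (sigma), > 0.
#' @param jitter per-locus Gaussian sd (sigma), >= 0.
#' @param intra_scale backbone step inside a cluster (sigma).
#' @param seed integer seed.
#' @return an [ensemble()]; `$provenance$junctions` records the per-structure
#'   junction actually used (ground truth).
#' @export
make_boundary_ensemble <- function(n_structures, n_loci, junction,
                                   separation = 10, jitter = 0.05,
                                   intra_scale = 0.3, seed = 1L) {
  if (separation <= 0) stop("separation must be > 0")
  junction <- as.integer(junction)
  if (any(junction <= 1L) || any(junction > n_loci))
    stop("junction must be in (1, n_loci]")
  set.seed(seed)
  coords <- array(0, dim = c(n_structures, n_loci, 3))
  jct <- junction[sample.int(length(junction), n_structures,
                             replace = TRUE)]
  for (m in seq_len(n_structures)) {
    j <- jct[m]
    # deterministic compact backbones (line segments along y, centred),
    # separated along x; all randomness is the per-locus jitter, so the
    # jitter -> 0 limit has bit-stable geometry in every structure
    i1 <- 1:(j - 1)
    i2 <- j:n_loci
    y <- numeric(n_loci)
    y[i1] <- (i1 - mean(i1)) * intra_scale
    y[i2] <- (i2 - mean(i2)) * intra_scale
    coords[m, , 2] <- y
    coords[m, i2, 1] <- separation
    coords[m, , ] <- coords[m, , ] + rnorm(n_loci * 3, 0, jitter)
  }
  ensemble(coords, provenance = list(generator = "make_boundary_ensemble",
                                     junctions = jct, seed = seed))
}

#' Ground truth bundle for a synthetic chromosome
#'
#' Collects the implanted TAD intervals, switch positions and compartment
#' labels so downstream tests can re-derive annotations from the data and
#' check consistency.
#'
#' @param tad_intervals half-open bin intervals (matrix start, end).
#' @param switch_positions block-junction bins.
#' @param compartment_labels per-locus A/B labels.
#' @export
ground_truth <- function(tad_intervals, switch_positions,
                         compartment_labels) {
  tad_intervals <- matrix(as.integer(tad_intervals), ncol = 2)
  if (nrow(tad_intervals) > 1) {
    o <- order(tad_intervals[, 1])
    tad_intervals <- tad_intervals[o, , drop = FALSE]
    if (any(tad_intervals[-1, 1] < tad_intervals[-nrow(tad_intervals), 2]))
      stop("ground-truth TADs overlap")
  }
  sw <- as.integer(switch_positions)
  if (length(sw)) {
    lab <- compartment_labels
    ok <- vapply(sw, function(p) p > 1 && p <= length(lab) &&
                   lab[p] != lab[p - 1], logical(1))
    if (!all(ok)) stop("switch_positions inconsistent with labels")
  }
  structure(list(tad_intervals = tad_intervals, switch_positions = sw,
                 compartment_labels = as.character(compartment_labels)),
            class = "ground_truth")
}
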
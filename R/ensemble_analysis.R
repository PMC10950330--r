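## Comparison quantities between structure ensembles and Hi-C style maps:
## contact maps, distance-stratified Z-scores, Pearson correlation maps,
## KL divergence of correlation distributions, PC1 compartments, the
## contact <-> distance power law, and Ward linkage matrices.

#' Contact map from a structure ensemble
#'
#' `C_ij` counts the structures in which loci i and j are closer than
#' `cutoff` (default 1.75 sigma). The diagonal is set to the number of
#' structures by convention; all distance-stratified statistics use
#' off-diagonal entries only.
#'
#' @param ens an [ensemble()].
#' @param cutoff contact distance threshold (sigma), > 0.
#' @return a [contact_map()].
#' @export
contact_map_from_ensemble <- function(ens, cutoff = 1.75) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (ens$n_structures < 1) stop("empty ensemble")
  n <- ens$n_loci
  C <- matrix(0, n, n)
  for (m in seq_len(ens$n_structures)) {
    d <- as.matrix(dist(ensemble_structure(ens, m)))
    C <- C + (d < cutoff)
  }
  diag(C) <- ens$n_structures
  res <- if (!is.null(ens$spec)) ens$spec$resolution_bp else 50000L
  contact_map(C, resolution_bp = res)
}

#' Mean spatial distance map from a structure ensemble
#'
#' @param ens an [ensemble()].
#' @return a [distance_map()] with provenance "measured".
#' @export
distance_map_from_ensemble <- function(ens) {
  if (ens$n_structures < 1) stop("empty ensemble")
  n <- ens$n_loci
  R <- matrix(0, n, n)
  for (m in seq_len(ens$n_structures))
    R <- R + as.matrix(dist(ensemble_structure(ens, m)))
  res <- if (!is.null(ens$spec)) ens$spec$resolution_bp else 50000L
  distance_map(R / ens$n_structures, resolution_bp = res,
               provenance = "measured")
}

#' Distance-stratified Z-score transform of a contact map
#'
#' Works on the natural-log scale, `log(C + 1)` (the +1 admits zero
#' counts). For each genomic separation s >= 1 the diagonal entries are
#' standardized: `Z_ij = (logC_ij - <logC_s>) / sd_s`. Diagonals with zero
#' spread map to 0 by convention; the main diagonal is left at 0. Missing
#' bins are excluded from the per-diagonal moments and their Z entries set
#' to 0.
#'
#' @param cm a [contact_map()] or plain symmetric matrix.
#' @param log_transform apply `log1p` first (set FALSE if `cm` is already
#'   on a log scale).
#' @return symmetric Z matrix with zero diagonal.
#' @export
zscore_transform <- function(cm, log_transform = TRUE) {
  C <- if (inherits(cm, "contact_map")) cm$C else as.matrix(cm)
  mask <- if (inherits(cm, "contact_map")) cm$mask else rep(FALSE, nrow(C))
  n <- nrow(C)
  L <- if (log_transform) log1p(C) else C
  Z <- matrix(0, n, n)
  for (s in seq_len(n - 1)) {
    i <- seq_len(n - s)
    j <- i + s
    ok <- !mask[i] & !mask[j]
    v <- L[cbind(i, j)]
    if (sum(ok) >= 2) {
      mu <- mean(v[ok])
      sg <- sd(v[ok])
      z <- if (sg > 0) (v - mu) / sg else rep(0, length(v))
    } else z <- rep(0, length(v))
    z[!ok] <- 0
    Z[cbind(i, j)] <- z
    Z[cbind(j, i)] <- z
  }
  Z
}

#' Pearson correlation map of Z-score profiles
#'
#' `rho_ij` is the Pearson correlation between the interaction profiles
#' (rows of the symmetric Z matrix) of loci i and j. Profiles with zero
#' variance (e.g. masked bins) give NA entries; the diagonal is 1 where
#' defined.
#'
#' @param Z square matrix, typically from [zscore_transform()].
#' @return correlation matrix in \[-1, 1\] with NA for undefined entries.
#' @export
pearson_map <- function(Z) {
  Z <- as.matrix(Z)
  if (nrow(Z) != ncol(Z)) stop("Z must be square")
  v <- apply(Z, 1, var)
  rho <- suppressWarnings(cor(t(Z)))
  rho[v == 0 | is.na(v), ] <- NA
  rho[, v == 0 | is.na(v)] <- NA
  diag(rho)[v > 0 & !is.na(v)] <- 1
  rho
}

#' Kullback-Leibler divergence between two samples of correlations
#'
#' Histograms both samples on a shared binning of \[-1, 1\] (default 50
#' equal bins), adds a pseudo-count of 1 to every bin before normalizing,
#' and returns `sum p log(p/q)` (natural log). Asymmetric in (p, q):
#' p is the reference ("experimental") distribution.
#'
#' @param p_values,q_values numeric samples (NAs dropped).
#' @param n_bins number of equal bins on `range`.
#' @param range histogram support.
#' @param pseudo_count added to every bin count.
#' @export
kl_divergence <- function(p_values, q_values, n_bins = 50,
                          range = c(-1, 1), pseudo_count = 1) {
  p_values <- p_values[is.finite(p_values)]
  q_values <- q_values[is.finite(q_values)]
  if (!length(p_values) || !length(q_values)) stop("empty sample")
  br <- seq(range[1], range[2], length.out = n_bins + 1)
  clamp <- function(x) pmin(pmax(x, range[1]), range[2])
  hp <- tabulate(findInterval(clamp(p_values), br, rightmost.closed = TRUE,
                              all.inside = TRUE), n_bins) + pseudo_count
  hq <- tabulate(findInterval(clamp(q_values), br, rightmost.closed = TRUE,
                              all.inside = TRUE), n_bins) + pseudo_count
  p <- hp / sum(hp)
  q <- hq / sum(hq)
  sum(p * log(p / q))
}

#' PC1 compartment signal from a Pearson correlation map
#'
#' First principal component of the correlation map (rows centred by
#' `prcomp`); masked/NA rows are mean-imputed before the PCA and reported
#' as NA in the output. When an A/B `states` track is supplied the sign is
#' oriented so A loci have positive mean PC1.
#'
#' @param rho correlation matrix from [pearson_map()].
#' @param states optional per-locus "A"/"B" labels for sign orientation.
#' @return list with `pc1` (per-locus signal), `var_explained`, and
#'   `flipped` (whether orientation changed sign).
#' @export
pc1_compartments <- function(rho, states = NULL) {
  rho <- as.matrix(rho)
  n <- nrow(rho)
  bad <- apply(rho, 1, function(r) all(is.na(r)))
  M <- rho
  M[is.na(M)] <- mean(rho, na.rm = TRUE)
  if (sd(as.vector(M)) == 0) stop("degenerate (constant) correlation map")
  pc <- prcomp(M, center = TRUE, scale. = FALSE)
  pc1 <- pc$x[, 1]
  flipped <- FALSE
  if (!is.null(states)) {
    if (length(states) != n) stop("states length mismatch")
    mA <- mean(pc1[states == "A" & !bad])
    if (is.finite(mA) && mA < 0) { pc1 <- -pc1; flipped <- TRUE }
  }
  pc1[bad] <- NA
  list(pc1 = pc1,
       var_explained = pc$sdev[1]^2 / sum(pc$sdev^2),
       flipped = flipped)
}

#' Convert contacts to mean spatial distances via the inverse power law
#'
#' Uses `R_ij` proportional to `P_ij^(-1/exponent)` with exponent 4.1, the
#' empirical relation between Hi-C contact probability and mean 3D
#' distance. Zero contacts are replaced by half the smallest positive
#' entry before inversion. The scale anchor sets the mean nearest-neighbour
#' (|i-j| = 1) distance to `scale`.
#'
#' @param cm a [contact_map()] or matrix.
#' @param exponent power-law exponent (> 0).
#' @param scale target mean nearest-neighbour distance (sigma).
#' @return a [distance_map()] with provenance "converted".
#' @export
contacts_to_distances <- function(cm, exponent = 4.1, scale = 1.0) {
  if (exponent <= 0) stop("exponent must be > 0")
  C <- if (inherits(cm, "contact_map")) cm$C else as.matrix(cm)
  res <- if (inherits(cm, "contact_map")) cm$resolution_bp else 50000L
  P <- C
  pos <- P[P > 0]
  if (!length(pos)) stop("contact map has no positive entries")
  P[P == 0] <- min(pos) / 2
  R <- P^(-1 / exponent)
  diag(R) <- 0
  n <- nrow(R)
  nn <- mean(R[cbind(1:(n - 1), 2:n)])
  distance_map(R * (scale / nn), resolution_bp = res,
               provenance = "converted")
}

#' Convert distances to relative contact frequencies
#'
#' Inverse of [contacts_to_distances()] up to scale:
#' `P_ij` proportional to `R_ij^(-exponent)`.
#'
#' @param dm a [distance_map()] or matrix.
#' @param exponent power-law exponent (> 0).
#' @param diag_value value placed on the diagonal (contacts with self).
#' @return a [contact_map()] of relative frequencies.
#' @export
distances_to_contacts <- function(dm, exponent = 4.1, diag_value = NULL) {
  if (exponent <= 0) stop("exponent must be > 0")
  R <- if (inherits(dm, "distance_map")) dm$R else as.matrix(dm)
  res <- if (inherits(dm, "distance_map")) dm$resolution_bp else 50000L
  off <- R[row(R) != col(R)]
  if (any(off <= 0)) stop("off-diagonal distances must be positive")
  P <- R^(-exponent)
  if (is.null(diag_value)) diag_value <- max(P[row(P) != col(P)])
  diag(P) <- diag_value
  contact_map(P, resolution_bp = res)
}

#' Ward linkage matrix of a spatial distance map
#'
#' Runs agglomerative clustering with Ward's criterion on the loci (the
#' distance map supplies the dissimilarities) and returns the cophenetic
#' matrix: `W_ij` is the merge height at which loci i and j first join a
#' common cluster. Masked loci (rows that are entirely zero/NA off the
#' diagonal) are excluded and reported.
#'
#' @param dm a [distance_map()] or symmetric matrix.
#' @return list with `W` (n x n matrix, NA for excluded loci), `excluded`
#'   (locus indices), and `hclust` (the tree).
#' @export
ward_linkage_matrix <- function(dm) {
  R <- if (inherits(dm, "distance_map")) dm$R else as.matrix(dm)
  n <- nrow(R)
  excluded <- which(vapply(seq_len(n), function(i)
    all(!is.finite(R[i, -i])), logical(1)))
  keep <- setdiff(seq_len(n), excluded)
  hc <- hclust(as.dist(R[keep, keep]), method = "ward.D2")
  Wk <- as.matrix(cophenetic(hc))
  W <- matrix(NA_real_, n, n)
  W[keep, keep] <- Wk
  diag(W)[keep] <- 0
  list(W = W, excluded = excluded, hclust = hc)
}

#' Pearson correlation between two Ward linkage matrices
#'
#' @param W1,W2 matrices (or outputs of [ward_linkage_matrix()]); compared
#'   on upper triangles, NA entries dropped pairwise.
#' @export
compare_wlm <- function(W1, W2) {
  if (is.list(W1)) W1 <- W1$W
  if (is.list(W2)) W2 <- W2$W
  if (!all(dim(W1) == dim(W2))) stop("dimension mismatch")
  u <- upper.tri(W1)
  cor(W1[u], W2[u], use = "pairwise.complete.obs")
}
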
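## Maximum-entropy 3D structure generation from a contact map alone.
##
## Pipeline: contact map -> mean distance targets via the P ~ R^-4.1 power
## law -> Gaussian-form maximum-entropy model
##     P({x}) propto exp(-sum_{i<j} k_ij r_ij^2)
## whose pairwise mean distances match the targets -> independent structure
## sampling -> contact-threshold calibration so recomputed maps agree with
## the input. The quadratic-constraint model stays in closed form: per
## Cartesian dimension the coordinates are multivariate normal with
## precision 2A, where A is the weighted graph Laplacian of the couplings,
## and <r_ij^2> = 3 (S_ii + S_jj - 2 S_ij) with S the (pseudo-)inverse
## covariance factor. Targets stated as mean distances are converted to
## second moments through the Gaussian identity <r> = sqrt(8/(3 pi))
## sqrt(<r^2>).

# covariance factor of the model (per dimension) and derived <r^2_ij>;
# the centre-of-mass zero mode is projected out
.maxent_moments <- function(K) {
  n <- nrow(K)
  A <- -K
  diag(A) <- 0
  diag(A) <- -rowSums(A)
  ev <- eigen(2 * A, symmetric = TRUE)
  vals <- ev$values
  # pseudo-inverse: drop the (single) zero mode; guard small negatives
  inv <- ifelse(vals > max(vals) * 1e-12, 1 / vals, 0)
  S <- ev$vectors %*% (inv * t(ev$vectors))
  d2 <- outer(diag(S), diag(S), "+") - 2 * S
  list(S = S, r2 = 3 * d2, eig = ev, inv = inv)
}

#' Fit the maximum-entropy coupling model to a distance target
#'
#' Iteratively updates the couplings `k_ij <- k_ij * (<r2_ij>/target2_ij)^eta`
#' (multiplicative, learning rate `eta = 0.5`) until the model's mean
#' distances match the target matrix within `tol` relative error (checked
#' on the median and on the per-pair maximum against `tol_max`). Backbone
#' (|i-j| = 1) couplings are floored at a small positive value so the
#' model always remains a proper connected Gaussian chain; other couplings
#' stay non-negative (pairs that should sit farther apart than the rest of
#' the network allows simply relax toward zero coupling).
#'
#' @param dm a [distance_map()] (or matrix) of target mean distances.
#' @param tol relative-error tolerance on the median pair (default 0.01).
#' @param tol99 tolerance on the 99th percentile of per-pair relative
#'   errors (default `5 * tol`); both must be met to declare convergence,
#'   so a few far-off pairs cannot hide behind a good median.
#' @param max_iter iteration cap.
#' @param eta learning rate of the multiplicative update.
#' @param k_backbone_min floor for backbone couplings.
#' @return object of class `maxent_model`: couplings `K`, `target` (mean
#'   distances), convergence `trace` (per-iteration median/max relative
#'   error), `converged` flag, and the worst pairs when not converged.
#' @export
fit_maxent <- function(dm, tol = 0.01, tol99 = 5 * tol, max_iter = 200L,
                       eta = 0.5, k_backbone_min = 1e-6) {
  R <- if (inherits(dm, "distance_map")) dm$R else as.matrix(dm)
  n <- nrow(R)
  off <- R[row(R) != col(R)]
  if (any(!is.finite(off)) || any(off <= 0))
    stop("targets must be positive and finite off the diagonal")
  # mean-distance -> second-moment targets (Gaussian identity)
  T2 <- (3 * pi / 8) * R^2
  diag(T2) <- 0
  # init: ideal-chain backbone scaled to the nearest-neighbour target
  K <- matrix(0, n, n)
  bb <- cbind(1:(n - 1), 2:n)
  K[bb] <- 3 / (2 * T2[bb])
  K[bb[, 2:1]] <- K[bb]
  # weak long-range seed so every pair participates in the update
  lr <- row(K) != col(K) & K == 0
  K[lr] <- 1e-4 * min(K[bb])
  trace <- data.frame(iter = integer(), median_rel = numeric(),
                      max_rel = numeric())
  rel <- NULL
  for (it in seq_len(max_iter)) {
    mom <- .maxent_moments(K)
    ratio <- mom$r2 / T2
    diag(ratio) <- 1
    rel <- abs(sqrt(mom$r2[upper.tri(T2)] / T2[upper.tri(T2)]) - 1)
    trace <- rbind(trace, data.frame(iter = it, median_rel = median(rel),
                                     max_rel = max(rel)))
    if (median(rel) <= tol && quantile(rel, 0.99) <= tol99) break
    K <- K * ratio^eta
    K[bb] <- pmax(K[bb], k_backbone_min)
    K[bb[, 2:1]] <- K[bb]
    K[K < 0] <- 0
  }
  mom <- .maxent_moments(K)
  rel_m <- abs(sqrt(mom$r2[upper.tri(T2)] / T2[upper.tri(T2)]) - 1)
  conv <- median(rel_m) <= tol && quantile(rel_m, 0.99) <= tol99
  worst <- NULL
  if (!conv) {
    ut <- which(upper.tri(T2), arr.ind = TRUE)
    o <- order(rel_m, decreasing = TRUE)[1:min(10, length(rel_m))]
    worst <- cbind(ut[o, , drop = FALSE], rel_error = rel_m[o])
  }
  structure(list(K = K, target = R, target2 = T2, trace = trace,
                 converged = conv, median_rel_error = median(rel_m),
                 worst_pairs = worst, n_loci = n),
            class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("maxent_model: %d loci, %s (median rel. error %.3g, %d iterations)\n",
              x$n_loci, if (x$converged) "converged" else "NOT converged",
              x$median_rel_error, nrow(x$trace)))
  invisible(x)
}

#' Sample independent structures from a maximum-entropy model
#'
#' Each Cartesian dimension is drawn independently from the model's
#' multivariate normal (zero-mean, centre of mass pinned at the origin).
#'
#' @param model a `maxent_model` from [fit_maxent()].
#' @param n_structures number of structures (0 gives an empty ensemble).
#' @param seed integer seed.
#' @return an [ensemble()].
#' @export
sample_structures <- function(model, n_structures, seed = 1L) {
  n <- model$n_loci
  mom <- .maxent_moments(model$K)
  if (sum(mom$inv > 0) < n - 1)
    stop("model is not normalizable (disconnected couplings)")
  set.seed(seed)
  # x = V sqrt(inv) z per dimension
  V <- mom$eig$vectors
  s <- sqrt(mom$inv)
  coords <- array(0, dim = c(max(n_structures, 0), n, 3))
  for (m in seq_len(n_structures))
    for (d in 1:3)
      coords[m, , d] <- as.vector(V %*% (s * rnorm(n)))
  ensemble(coords, provenance = list(generator = "maxent", seed = seed))
}

#' Calibrate the contact threshold against a reference map
#'
#' Scans thresholds over `grid` (in units of the ensemble's mean
#' nearest-neighbour distance), recomputes the contact map at each, and
#' returns the threshold maximizing the Pearson correlation of
#' `log(1 + map)` upper triangles with the reference (ties broken by the
#' closest total contact density). This is the step that adjusts the
#' distance threshold for contact until the recomputed map best matches
#' the input.
#'
#' @param ens an [ensemble()].
#' @param reference a [contact_map()] congruent with the ensemble.
#' @param grid threshold multipliers (default 0.5-3.0 by 0.05).
#' @return list: `threshold` (absolute, sigma), `objective` (PCC at the
#'   optimum), `scan` (data.frame threshold/pcc/density), and `map` (the
#'   recomputed [contact_map()] at the optimum).
#' @export
calibrate_contact_threshold <- function(ens, reference,
                                        grid = seq(0.5, 3.0, by = 0.05)) {
  refC <- if (inherits(reference, "contact_map")) reference$C else
    as.matrix(reference)
  if (nrow(refC) != ens$n_loci) stop("reference and ensemble not congruent")
  u <- upper.tri(refC)
  ref_log <- log1p(refC[u])
  if (sd(ref_log) == 0) stop("degenerate reference map")
  ref_density <- mean(refC[u] / max(refC[u], 1))
  n <- ens$n_loci
  # precompute distances once; thresholding is then a cheap count
  dsum <- vector("list", ens$n_structures)
  for (m in seq_len(ens$n_structures))
    dsum[[m]] <- dist(ensemble_structure(ens, m))
  dnn <- mean(vapply(seq_len(ens$n_structures), function(m) {
    D <- as.matrix(dsum[[m]])
    mean(D[cbind(1:(n - 1), 2:n)])
  }, numeric(1)))
  scan <- data.frame(threshold = grid * dnn, pcc = NA_real_,
                     density = NA_real_)
  best <- NULL
  for (g in seq_along(grid)) {
    thr <- grid[g] * dnn
    C <- matrix(0, n, n)
    for (m in seq_len(ens$n_structures))
      C <- C + (as.matrix(dsum[[m]]) < thr)
    diag(C) <- ens$n_structures
    cl <- log1p(C[u])
    scan$pcc[g] <- if (sd(cl) > 0) cor(cl, ref_log) else NA_real_
    scan$density[g] <- mean(C[u] / ens$n_structures)
  }
  ok <- which(is.finite(scan$pcc))
  if (!length(ok)) stop("no threshold produced a non-degenerate map")
  top <- ok[scan$pcc[ok] >= max(scan$pcc[ok]) - 1e-12]
  if (length(top) > 1)
    top <- top[which.min(abs(scan$density[top] - ref_density))]
  thr <- scan$threshold[top]
  C <- matrix(0, n, n)
  for (m in seq_len(ens$n_structures))
    C <- C + (as.matrix(dsum[[m]]) < thr)
  diag(C) <- ens$n_structures
  res <- if (inherits(reference, "contact_map"))
    reference$resolution_bp else 50000L
  list(threshold = thr, objective = scan$pcc[top], scan = scan,
       map = contact_map(C, resolution_bp = res))
}

#' HIPPS-lite: structures from a contact map alone
#'
#' Convenience pipeline: contact map -> distance targets (power law,
#' exponent 4.1) -> [fit_maxent()] -> [sample_structures()] ->
#' [calibrate_contact_threshold()] against the input map.
#'
#' @param cm a [contact_map()].
#' @param n_structures ensemble size.
#' @param seed integer seed.
#' @param exponent contact-to-distance power-law exponent.
#' @param tol,max_iter passed to [fit_maxent()].
#' @param calibrate also run the threshold calibration (default TRUE).
#' @return list: `model`, `ensemble`, `distance_targets`, and (when
#'   calibrated) `threshold`, `recomputed_map`, `map_pcc`.
#' @export
hipps_structures <- function(cm, n_structures = 400L, seed = 1L,
                             exponent = 4.1, tol = 0.01, max_iter = 200L,
                             calibrate = TRUE) {
  dm <- contacts_to_distances(cm, exponent = exponent)
  model <- fit_maxent(dm, tol = tol, max_iter = max_iter)
  ens <- sample_structures(model, n_structures, seed = seed)
  out <- list(model = model, ensemble = ens, distance_targets = dm)
  if (calibrate) {
    cal <- calibrate_contact_threshold(ens, cm)
    out$threshold <- cal$threshold
    out$recomputed_map <- cal$map
    out$map_pcc <- cal$objective
  }
  out
}
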
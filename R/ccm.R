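## Chromosome copolymer model: energy terms, reduced-unit scaling and the
## two-phase Langevin protocol.
##
## Energy scale is kBT; length scale is the bead diameter sigma at the
## working resolution. The A-A and B-B attractions share a common well depth
## eps, and the A-B depth is eps / 1.19, the weaker cross-attraction that
## drives A/B micro-phase separation in the Flory-Huggins picture. Both are
## configurable.

#' Force field for the chromosome copolymer model
#'
#' Defaults are the 50-kb-resolution bonding constants (FENE spring
#' 2.497 kBT/sigma^2 with maximum extension 5.199 sigma; loop-anchor
#' harmonic spring 24.97 kBT/sigma^2 with rest length 3.916 sigma) and
#' eps_AA = eps_BB = 1 kBT with eps_AB = eps/1.19.
#'
#' @param k_fene FENE spring constant (kBT/sigma^2).
#' @param r0_fene FENE maximum extension (sigma).
#' @param eps common A-A/B-B Lennard-Jones well depth (kBT).
#' @param eps_ratio ratio eps / eps_AB (> 1 weakens the cross attraction).
#' @param eps_aa,eps_bb,eps_ab explicit overrides of the well depths.
#' @param sigma Lennard-Jones diameter (1 by definition of the length unit).
#' @param rc Lennard-Jones cutoff (sigma).
#' @param k_h loop-anchor spring constant (kBT/sigma^2).
#' @param r0_h loop-anchor rest length (sigma).
#' @export
ccm_force_field <- function(k_fene = 2.497, r0_fene = 5.199,
                            eps = 1.0, eps_ratio = 1.19,
                            eps_aa = eps, eps_bb = eps,
                            eps_ab = eps / eps_ratio,
                            sigma = 1.0, rc = 2.5,
                            k_h = 24.97, r0_h = 3.916) {
  stopifnot(k_fene > 0, k_h > 0, r0_fene > 0, sigma > 0,
            eps_aa > 0, eps_bb > 0, eps_ab > 0)
  structure(list(k_fene = k_fene, r0_fene = r0_fene,
                 eps_aa = eps_aa, eps_bb = eps_bb, eps_ab = eps_ab,
                 sigma = sigma, rc = rc, k_h = k_h, r0_h = r0_h),
            class = "ccm_force_field")
}

#' Simulation parameters for the two-phase Langevin protocol
#'
#' Phase 1 ("push-off") relaxes the start conformation against the purely
#' repulsive (WCA) pair interactions, the bonds and the loop restraints by
#' capped steepest descent: each iteration moves every bead by
#' `force x dt_soft`, truncated to `max_move_soft`. This is quasi-static,
#' so stiff loop springs reel distant anchors in without accumulating
#' momentum, and bonds stay inside the FENE domain. Phase 2 draws fresh
#' thermal velocities and integrates the full force field at `dt_main` for
#' `n_equil` equilibration steps followed by `n_prod` production steps,
#' sampling a frame every `sample_every` steps.
#'
#' @param zeta friction coefficient (m/tau). Equilibrium averages do not
#'   depend on it.
#' @param kbt thermal energy (1 in reduced units).
#' @param mass bead mass (1 in reduced units).
#' @param dt_soft,n_soft push-off descent mobility (tau) and iteration
#'   count.
#' @param dt_main main time step (tau).
#' @param n_equil,n_prod equilibration / production step counts.
#' @param sample_every production steps between saved frames.
#' @param max_move_soft displacement cap per step during push-off (sigma).
#' @param seed integer seed for the trajectory RNG.
#' @export
ccm_sim_params <- function(zeta = 0.01, kbt = 1, mass = 1,
                           dt_soft = 1e-4, n_soft = 10000L,
                           dt_main = 1e-2, n_equil = 500000L,
                           n_prod = 500000L, sample_every = 2500L,
                           max_move_soft = 0.05, seed = 1L) {
  stopifnot(dt_soft < dt_main, n_soft >= 0, n_equil >= 0, n_prod >= 0,
            zeta > 0, mass > 0, kbt > 0)
  structure(list(zeta = zeta, kbt = kbt, mass = mass,
                 dt_soft = dt_soft, n_soft = as.integer(n_soft),
                 dt_main = dt_main, n_equil = as.integer(n_equil),
                 n_prod = as.integer(n_prod),
                 sample_every = as.integer(sample_every),
                 max_move_soft = max_move_soft, seed = as.integer(seed)),
            class = "ccm_sim_params")
}

#' FENE bond energy
#'
#' `U(r) = -1/2 K R0^2 log(1 - (r/R0)^2)`; finite extensibility means the
#' energy diverges as r approaches R0 and r >= R0 is a domain error.
#'
#' @param r bond length (sigma), 0 <= r < R0. Vectorized.
#' @param k spring constant (kBT/sigma^2).
#' @param r0 maximum extension (sigma).
#' @export
fene_energy <- function(r, k = 2.497, r0 = 5.199) {
  if (any(r < 0)) stop("r must be >= 0")
  if (any(r >= r0)) stop("bond overstretched: r >= R0")
  -0.5 * k * r0^2 * log(1 - (r / r0)^2)
}

#' Lennard-Jones pair energy
#'
#' `U(r) = 4 eps ((sigma/r)^12 - (sigma/r)^6)`. Vectorized; r = 0 is a
#' domain error.
#'
#' @param r pair distance (> 0).
#' @param eps well depth (kBT).
#' @param sigma diameter (sigma).
#' @export
lj_energy <- function(r, eps = 1, sigma = 1) {
  if (any(r <= 0)) stop("r must be > 0")
  sr6 <- (sigma / r)^6
  4 * eps * (sr6^2 - sr6)
}

#' Harmonic loop-anchor energy
#'
#' `U(r) = K_h (r - r0_h)^2` for a CTCF loop-anchor pair held by cohesin.
#'
#' @param r anchor separation (>= 0). Vectorized.
#' @param k_h spring constant (kBT/sigma^2).
#' @param r0_h rest length (sigma).
#' @export
loop_energy <- function(r, k_h = 24.97, r0_h = 3.916) {
  if (any(r < 0)) stop("r must be >= 0")
  k_h * (r - r0_h)^2
}

#' Total copolymer energy of a conformation
#'
#' Sum of FENE over consecutive pairs, Lennard-Jones over all non-bonded
#' pairs (j >= i + 2; the bonded neighbour is excluded because the FENE term
#' already restrains it -- set `exclude_bonded_lj = FALSE` to include it),
#' with the well depth picked by the (A/B, A/B) types, plus harmonic terms
#' over the anchor pairs present under the spec's loop occupancy. No LJ
#' cutoff is applied here (this is the exact lattice of Eq-level terms used
#' by the energy oracle tests); the dynamics engine truncates at `ff$rc`.
#'
#' @param conformation N x 3 coordinate matrix.
#' @param spec a [chromosome_spec()]; `spec$pl` of 1/0 includes/excludes the
#'   loop sum, intermediate values include every anchor (per-structure
#'   thinning is a sampling question, handled by [run_langevin()]).
#' @param ff a [ccm_force_field()].
#' @param exclude_bonded_lj drop j = i + 1 from the LJ sum (default TRUE).
#' @return energy in kBT.
#' @export
total_energy <- function(conformation, spec, ff = ccm_force_field(),
                         exclude_bonded_lj = TRUE) {
  xyz <- as.matrix(conformation)
  n <- nrow(xyz)
  if (n != spec$n_loci) stop("conformation does not match spec size")
  d <- as.matrix(dist(xyz))
  bond <- d[cbind(1:(n - 1), 2:n)]
  e_fene <- sum(fene_energy(bond, ff$k_fene, ff$r0_fene))
  typ <- as.integer(spec$states == "B")  # A=0, B=1
  epsm <- matrix(c(ff$eps_aa, ff$eps_ab, ff$eps_ab, ff$eps_bb), 2)
  ut <- which(upper.tri(d), arr.ind = TRUE)
  gap <- ut[, 2] - ut[, 1]
  keep <- if (exclude_bonded_lj) gap >= 2 else gap >= 1
  ut <- ut[keep, , drop = FALSE]
  e_lj <- if (nrow(ut)) {
    eps_ij <- epsm[cbind(typ[ut[, 1]] + 1L, typ[ut[, 2]] + 1L)]
    sum(4 * eps_ij * ((ff$sigma / d[ut])^12 - (ff$sigma / d[ut])^6))
  } else 0
  e_loop <- 0
  if (spec$pl > 0 && nrow(spec$loop_anchors)) {
    ra <- d[spec$loop_anchors]
    e_loop <- sum(loop_energy(ra, ff$k_h, ff$r0_h))
  }
  e_fene + e_lj + e_loop
}

#' Reduced-unit scaling between bin resolutions
#'
#' A locus with `Nbp` base pairs is treated as a condensed polymer with
#' radius of gyration Rg ~ Nbp^(1/3), so the bead size scales as the cube
#' root of the base-pair content and the mass linearly. Scaling 1,200 bp
#' beads to 50,000 bp gives size factor 3.466 and mass factor 41.66.
#'
#' @param target_bp,reference_bp base pairs per bead.
#' @return list with `size_factor` and `mass_factor`.
#' @export
scale_parameters <- function(target_bp, reference_bp) {
  stopifnot(target_bp > 0, reference_bp > 0)
  list(size_factor = (target_bp / reference_bp)^(1 / 3),
       mass_factor = target_bp / reference_bp)
}

#' Self-avoiding random-walk initial conformation
#'
#' Grows a chain with fixed bond length and rejects steps that come within
#' `min_sep` of any previous bead (with a bounded number of retries, after
#' which the constraint is relaxed -- the push-off phase removes residual
#' overlap anyway).
#'
#' @param n_loci chain length.
#' @param bond bond length (sigma).
#' @param min_sep minimum allowed distance to previous beads (sigma).
#' @param seed integer seed.
#' @return N x 3 matrix.
#' @export
initial_conformation <- function(n_loci, bond = 1.0, min_sep = 0.9,
                                 seed = 1L) {
  set.seed(seed)
  xyz <- matrix(0, n_loci, 3)
  for (i in seq_len(n_loci)[-1]) {
    for (try in 1:50) {
      u <- rnorm(3)
      step <- bond * u / sqrt(sum(u^2))
      cand <- xyz[i - 1, ] + step
      d2 <- rowSums((xyz[1:(i - 1), , drop = FALSE] -
                       matrix(cand, i - 1, 3, byrow = TRUE))^2)
      if (all(d2 > min_sep^2) || try == 50) break
    }
    xyz[i, ] <- cand
  }
  xyz
}

#' Run the two-phase Langevin dynamics of the copolymer model
#'
#' Integrates the Langevin equation (BAOAB splitting; zero-mean random
#' force obeying the fluctuation-dissipation relation with friction `zeta`)
#' for the chain defined by `spec` under `ff`, using the push-off +
#' production protocol in `params`. Loop anchors are restrained according
#' to `spec$pl`: all at `pl = 1`, none at `pl = 0`, otherwise each anchor
#' is kept independently with probability `pl` (drawn once per run, from
#' `params$seed`).
#'
#' @param spec a [chromosome_spec()].
#' @param ff a [ccm_force_field()].
#' @param params a [ccm_sim_params()].
#' @param x0 optional N x 3 initial conformation; default a self-avoiding
#'   walk seeded from `params$seed`.
#' @return an [ensemble()] of production frames; `$provenance` records the
#'   parameters, the restrained anchors and the mean kinetic temperature
#'   over production (should sit at `kbt`).
#' @export
run_langevin <- function(spec, ff = ccm_force_field(),
                         params = ccm_sim_params(), x0 = NULL) {
  if (is.null(x0))
    x0 <- initial_conformation(spec$n_loci, bond = 1.0, seed = params$seed)
  x0 <- as.matrix(x0)
  if (nrow(x0) != spec$n_loci) stop("x0 does not match spec size")
  anchors <- spec$loop_anchors
  if (nrow(anchors) && spec$pl < 1) {
    if (spec$pl == 0) {
      anchors <- anchors[integer(), , drop = FALSE]
    } else {
      set.seed(params$seed + 7L)
      keep <- runif(nrow(anchors)) < spec$pl
      anchors <- anchors[keep, , drop = FALSE]
    }
  }
  typ <- as.integer(spec$states == "B")
  res <- .ccm_run_cpp(x0, typ, anchors,
                      ff$k_fene, ff$r0_fene,
                      ff$eps_aa, ff$eps_bb, ff$eps_ab,
                      ff$sigma, ff$rc, ff$k_h, ff$r0_h,
                      params$zeta, params$mass, params$kbt,
                      params$dt_soft, params$n_soft,
                      params$dt_main, params$n_equil, params$n_prod,
                      params$sample_every, params$max_move_soft,
                      as.double(params$seed))
  frames <- res$frames
  final <- res$final
  if (params$n_soft == 0 && params$n_equil == 0 && params$n_prod == 0)
    final <- x0  # nothing integrated: conformation returned intact
  ensemble(frames, spec = spec,
           provenance = list(engine = "ccm_langevin",
                             force_field = unclass(ff),
                             params = unclass(params),
                             anchors_restrained = anchors,
                             final_conformation = final,
                             kinetic_temperature = res$kinetic_temperature))
}

#' Pool production frames from independent Langevin trajectories
#'
#' Runs `n_traj` trajectories that differ only in their seed (derived as
#' `params$seed + 1000 * (k - 1)`) and concatenates their production
#' frames. Independent replicas emulate the cell-to-cell variability of a
#' structural ensemble far better than a single trajectory, whose frames
#' share long-lived chain crumples.
#'
#' @inheritParams run_langevin
#' @param n_traj number of independent trajectories.
#' @return an [ensemble()] with pooled frames; per-trajectory kinetic
#'   temperatures are kept in `$provenance`.
#' @export
run_langevin_ensemble <- function(spec, ff = ccm_force_field(),
                                  params = ccm_sim_params(), n_traj = 4L) {
  stopifnot(n_traj >= 1)
  runs <- vector("list", n_traj)
  for (k in seq_len(n_traj)) {
    pk <- params
    pk$seed <- params$seed + 1000L * (k - 1L)
    runs[[k]] <- run_langevin(spec, ff, pk)
  }
  coords <- do.call(abind3, lapply(runs, function(e) e$coords))
  ensemble(coords, spec = spec,
           provenance = list(engine = "ccm_langevin_pooled",
                             n_traj = n_traj,
                             force_field = unclass(ff),
                             params = unclass(params),
                             kinetic_temperature = vapply(
                               runs, function(e)
                                 e$provenance$kinetic_temperature,
                               numeric(1))))
}

# bind arrays along the first (structure) dimension
abind3 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  total <- sum(vapply(xs, function(a) dim(a)[1], numeric(1)))
  out <- array(0, dim = c(total, d[2], d[3]))
  at <- 0L
  for (a in xs) {
    if (dim(a)[1] > 0) out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}
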
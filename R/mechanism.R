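## Desk-scale reproduction of the loop-deletion mechanism: a copolymer
## chromosome with alternating A/B blocks plus CTCF loop restraints is
## simulated with loops present (wild type) and deleted (cohesin
## depleted); TADs are called on both contact maps, matched, classified
## by epigenetic switch, and the spatial clustering of A loci is compared
## between conditions.

#' Loop-deletion mechanism fixture on a desk-scale copolymer chromosome
#'
#' Study conditions (fixed defaults): a 200-locus chain of five
#' alternating 40-bin A/B blocks; a loop-only domain held by nested
#' anchors inside the first (homogeneous A) block; a corner loop on the
#' switch-bounded fourth block. Each condition pools production frames
#' from `n_traj` independent trajectories (30 by default: chain crumples
#' are frozen per trajectory, so their spurious insulation dips average
#' down like 1/n_traj while the A/B-interface dips, common to every
#' replica, stay); every trajectory is equilibrated in two stages
#' (annealing): a mobile stage at a weaker well depth `eps_anneal`,
#' then the full `eps`, before production. The annealing stage lets the
#' A/B blocks find their micro-phase-separated arrangement before the
#' deeper quench would trap crumples.
#'
#' @param seed integer seed (all trajectory seeds derive from it).
#' @param n_traj independent trajectories per condition.
#' @param eps_anneal,eps well depths (kBT) of the two equilibration
#'   stages.
#' @param n_equil1,n_equil2,n_prod steps of the annealing stage, the
#'   full-strength equilibration, and production (per trajectory).
#' @param sample_every production steps between frames.
#' @param n_cluster_structures structures per condition used for the
#'   DBSCAN A-cluster count.
#' @return list: `tads` (wt/dep [tad_set()]s), `ptads` (annotated
#'   match records), `switches`, `loop_only_domain` (bin interval),
#'   `maps`, `ensembles`, `n_clusters_A` (named wt/dep means), and
#'   `dbscan_eps` used.
#' @export
ccm_mechanism_fixture <- function(seed = 2024L, n_traj = 30L,
                                  eps_anneal = 1.0, eps = 1.5,
                                  n_equil1 = 40000L, n_equil2 = 40000L,
                                  n_prod = 40000L, sample_every = 500L,
                                  n_cluster_structures = 30L) {
  states <- make_epigenetic_sequence(rep(40L, 5), "A")$states
  loop_only <- c(11L, 31L)  # domain [11, 31) in the first A block
  anchors <- rbind(c(11L, 30L), c(11L, 20L), c(20L, 30L),  # nested
                   c(121L, 160L))                          # switch-TAD corner
  ff_weak <- ccm_force_field(eps = eps_anneal)
  ff_full <- ccm_force_field(eps = eps)

  run_cond <- function(pl, seed_offset) {
    spec <- chromosome_spec(states, loop_anchors = anchors, pl = pl)
    frames <- vector("list", n_traj)
    for (k in seq_len(n_traj)) {
      s <- seed + seed_offset + 1000L * (k - 1L)
      stageA <- run_langevin(spec, ff_weak,
        ccm_sim_params(n_soft = 5000L, n_equil = n_equil1, n_prod = 0L,
                       seed = s))
      stageB <- run_langevin(spec, ff_full,
        ccm_sim_params(n_soft = 0L, n_equil = n_equil2, n_prod = n_prod,
                       sample_every = sample_every, seed = s + 7L),
        x0 = stageA$provenance$final_conformation)
      frames[[k]] <- stageB$coords
    }
    ensemble(do.call(abind3, frames), spec = spec,
             provenance = list(engine = "ccm_mechanism", pl = pl,
                               seed = seed, n_traj = n_traj))
  }

  ens_wt <- run_cond(1, 0L)
  ens_dep <- run_cond(0, 101L)
  cm_wt <- contact_map_from_ensemble(ens_wt)
  cm_dep <- contact_map_from_ensemble(ens_dep)
  tads_wt <- missing_bin_filter(call_tads(cm_wt, condition = "WT"), cm_wt)
  tads_dep <- missing_bin_filter(call_tads(cm_dep, condition = "depleted"),
                                 cm_dep)
  ptads <- match_ptads(tads_wt, tads_dep)
  sw <- detect_switches(states)
  ptads <- classify_switch_ptads(ptads, sw, states)

  # DBSCAN A-cluster counts: one eps per (type-agnostic) chromosome,
  # taken from the WT k-distance elbow and reused for the depleted
  # condition so the counts are comparable
  pick <- function(ens) round(seq(1, ens$n_structures,
                                  length.out = n_cluster_structures))
  eps_db <- median(vapply(pick(ens_wt), function(m)
    kdistance_elbow(ensemble_structure(ens_wt, m))$eps, numeric(1)))
  countA <- function(ens) {
    mean(vapply(pick(ens), function(m)
      dbscan_clusters(ensemble_structure(ens, m), states,
                      eps = eps_db)$n_clusters[["A"]], numeric(1)))
  }
  nA <- c(wt = countA(ens_wt), dep = countA(ens_dep))

  list(tads = list(wt = tads_wt, dep = tads_dep), ptads = ptads,
       switches = sw, loop_only_domain = loop_only,
       maps = list(wt = cm_wt, dep = cm_dep),
       ensembles = list(wt = ens_wt, dep = ens_dep),
       n_clusters_A = nA, dbscan_eps = eps_db,
       states = states, anchors = anchors, seed = seed)
}
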
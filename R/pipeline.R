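## Umbrella pipeline: synthetic chromosome (or copolymer simulation) under
## wild-type and loop-depleted conditions -> contact maps -> TAD calls ->
## P-TAD matching -> switch classification -> 3D boundary probabilities ->
## support annotation -> single report.

#' Default pipeline configuration
#'
#' `mode = "synthetic"` builds analytic contact maps (fast; loop-anchored
#' TADs become `tad_enrichment` squares that vanish in the depleted map,
#' compartment checkerboard stays); `mode = "ccm"` runs the copolymer
#' Langevin simulations at `pl = 1` and `pl = 0` and computes maps from
#' the sampled structures. 3D boundary probabilities come from HIPPS-lite
#' ensembles in synthetic mode and from the simulated structures in ccm
#' mode.
#'
#' @param ... overrides of the defaults (same names as the list below).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    mode = "synthetic",
    seed = 1L,
    n_loci = 200L,
    resolution_bp = 50000L,
    # A/B layout: block lengths in bins; switch-bounded middle B block
    block_lengths = c(80L, 60L, 60L),
    first_state = "A",
    # loops: switch-bounded TAD spanning the B block + loop-only TAD
    loop_anchors = rbind(c(81L, 140L), c(21L, 50L)),
    # synthetic-map parameters
    p0 = 100, decay_exponent = 1.0, tad_enrichment = 3,
    compartment_enrichment = 1.3, noise = "poisson",
    # caller / matcher
    w = 5L, alpha = 0.05, window_bins = 1L, min_overlap = 0.8,
    max_gap_bp = 100000, purity = 0.70,
    # structures
    hipps_n_structures = 200L, strength_threshold = 1.2,
    z_threshold = 0.7,
    # ccm mode
    ccm_params = NULL, ccm_force_field = NULL,
    contact_cutoff = 1.75)
  modifyList(cfg, list(...))
}

#' Run the preserved-TAD pipeline on synthetic data
#'
#' Executes, in dependency order: data generation (two conditions) ->
#' contact maps -> TopDom-style TAD calls with the missing-bin filter ->
#' P-TAD matching -> epigenetic-switch classification (filters I-III) ->
#' 3D structure ensembles -> boundary probabilities -> physical-boundary
#' support. Deterministic for a fixed config.
#'
#' @param config a [pipeline_config()].
#' @return list of class `ptad_report`: the `report` data.frame of summary
#'   numbers, per-stage objects (`maps`, `tads`, `ptads`, `profiles`), and
#'   the `config` (with seed) for the manifest.
#' @export
pipeline_run <- function(config = pipeline_config()) {
  seqs <- make_epigenetic_sequence(config$block_lengths, config$first_state)
  states <- seqs$states
  n <- length(states)
  spec_wt <- chromosome_spec(states, config$resolution_bp,
                             config$loop_anchors, pl = 1)
  spec_dep <- chromosome_spec(states, config$resolution_bp,
                              config$loop_anchors, pl = 0)
  anchors <- spec_wt$loop_anchors
  tad_iv <- cbind(anchors[, 1], anchors[, 2] + 1L)  # loop [p,q] spans bins p..q

  if (config$mode == "synthetic") {
    cm_wt <- make_block_contact_map(
      spec_wt, tads = tad_iv, p0 = config$p0,
      decay_exponent = config$decay_exponent,
      tad_enrichment = config$tad_enrichment,
      compartment_enrichment = config$compartment_enrichment,
      noise = config$noise, seed = config$seed)
    cm_dep <- make_block_contact_map(
      spec_dep, tads = matrix(integer(), ncol = 2), p0 = config$p0,
      decay_exponent = config$decay_exponent,
      tad_enrichment = 1,
      compartment_enrichment = config$compartment_enrichment,
      noise = config$noise, seed = config$seed + 1L)
    h_wt <- hipps_structures(cm_wt, config$hipps_n_structures,
                             seed = config$seed, calibrate = FALSE)
    h_dep <- hipps_structures(cm_dep, config$hipps_n_structures,
                              seed = config$seed + 1L, calibrate = FALSE)
    ens_wt <- h_wt$ensemble
    ens_dep <- h_dep$ensemble
  } else if (config$mode == "ccm") {
    ff <- if (is.null(config$ccm_force_field)) ccm_force_field() else
      config$ccm_force_field
    par0 <- if (is.null(config$ccm_params)) ccm_sim_params() else
      config$ccm_params
    par_wt <- par0; par_wt$seed <- config$seed
    par_dep <- par0; par_dep$seed <- config$seed + 1L
    ens_wt <- run_langevin(spec_wt, ff, par_wt)
    ens_dep <- run_langevin(spec_dep, ff, par_dep)
    cm_wt <- contact_map_from_ensemble(ens_wt, config$contact_cutoff)
    cm_dep <- contact_map_from_ensemble(ens_dep, config$contact_cutoff)
  } else stop("unknown mode: ", config$mode)

  tads_wt <- missing_bin_filter(
    call_tads(cm_wt, config$w, config$alpha, "WT"), cm_wt)
  tads_dep <- missing_bin_filter(
    call_tads(cm_dep, config$w, config$alpha, "depleted"), cm_dep)
  ptads <- match_ptads(tads_wt, tads_dep, config$window_bins,
                       config$min_overlap)
  sw <- detect_switches(states)
  ptads <- classify_switch_ptads(ptads, sw, states,
                                 config$resolution_bp,
                                 config$max_gap_bp, config$purity)
  prof_wt <- boundary_probability(ens_wt, config$strength_threshold)
  prof_dep <- boundary_probability(ens_dep, config$strength_threshold)
  ptads <- ptad_boundary_support(ptads, prof_wt, prof_dep,
                                 config$window_bins, config$z_threshold)

  n_wt <- nrow(tads_wt$intervals)
  n_pt <- sum(ptads$preserved)
  report <- data.frame(
    n_tads_wt = n_wt,
    n_tads_dep = nrow(tads_dep$intervals),
    n_ptads = n_pt,
    frac_preserved = if (n_wt) n_pt / n_wt else NA_real_,
    n_switch_ptads = sum(ptads$switch_status == "switch-preserved"),
    frac_switch = if (n_pt)
      sum(ptads$switch_status == "switch-preserved") / n_pt else NA_real_,
    n_supported = sum(ptads$boundary_support == "physical-boundary"),
    frac_supported = if (n_pt)
      sum(ptads$boundary_support == "physical-boundary") / n_pt else
        NA_real_)
  structure(list(report = report,
                 maps = list(wt = cm_wt, dep = cm_dep),
                 tads = list(wt = tads_wt, dep = tads_dep),
                 ptads = ptads,
                 profiles = list(wt = prof_wt, dep = prof_dep),
                 states = states, switches = sw,
                 config = config),
            class = "ptad_report")
}

#' @export
print.ptad_report <- function(x, ...) {
  cat("ptad_report:\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}
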
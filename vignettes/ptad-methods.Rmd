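---
title: "Preserved TADs after cohesin depletion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preserved TADs after cohesin depletion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

Hi-C maps of interphase chromosomes show two organizational scales: a
megabase-scale checkerboard of A/B compartments driven by the spatial
segregation of euchromatin and heterochromatin, and sub-megabase
topologically associating domains (TADs) that appear as enriched squares
along the diagonal. Degrading cohesin (or its loader) erases most TADs
while compartments persist or sharpen — yet a reproducible minority of
TADs survives. `ptadsuite` implements the computational machinery needed
to ask *why*: a chromosome copolymer simulator in which CTCF/cohesin
loops can be switched off, contact-map analytics, a TopDom-style TAD
caller with preserved-TAD (P-TAD) matching and an epigenetic-switch
classifier, single-structure boundary statistics, and a maximum-entropy
generator that produces 3D structure ensembles from a contact map alone.
Everything runs on synthetic chromosomes with known ground truth, so the
full inference chain is testable without external downloads.

The mechanistic claims the package can reproduce at desk scale are:

1. a TAD whose boundaries coincide with a switch in the A/B epigenetic
   state survives loop deletion, because micro-phase separation keeps
   insulating the boundary after the loop is gone;
2. a loop-only TAD inside an epigenetically homogeneous block dissolves
   when its loop is removed;
3. many surviving TADs have *physical* boundaries: sharp spatial
   junctions visible in single 3D structures, quantified by boundary
   probabilities.

# The chromosome copolymer model

A chromosome is a self-avoiding chain of beads (one per genomic bin;
50 kb by default). The energy has three terms:

* **FENE bonds** between consecutive beads,
  $U_{FENE}(r) = -\tfrac12 K R_0^2 \log(1 - r^2/R_0^2)$, with
  $K = 2.497\,k_BT/\sigma^2$ and $R_0 = 5.199\,\sigma$ at 50-kb
  resolution.
* **Lennard-Jones attraction** between non-bonded beads,
  $U_{LJ}(r) = 4\epsilon_{\alpha\beta}[(\sigma/r)^{12}-(\sigma/r)^6]$,
  where $\alpha,\beta \in \{A,B\}$. We use
  $\epsilon_{AA}=\epsilon_{BB}=\epsilon$ and
  $\epsilon/\epsilon_{AB} = 1.19$: the weaker cross attraction is the
  Flory-Huggins driving force for A/B segregation.
* **Harmonic loop restraints** on CTCF anchor pairs,
  $U_h(r) = K_h (r - r_{0,h})^2$ with $K_h = 24.97\,k_BT/\sigma^2$ and
  $r_{0,h} = 3.916\,\sigma$. Loop occupancy `PL` = 1 restrains every
  anchor (wild type), 0 none (cohesin depleted).

Bead size and mass scale between resolutions by the condensed-polymer
rule $R_g \sim N_{bp}^{1/3}$: going from 1.2-kb to 50-kb beads gives a
size factor $({50000}/{1200})^{1/3} = 3.466$ and a mass factor 41.66
(`scale_parameters()`).

**Choice of the absolute $\epsilon$.** Only the ratio
$\epsilon/\epsilon_{AB}$ is fixed by the model; the absolute well depth
is a calibration parameter (in the original application it was tuned
against experimental Hi-C, which a self-contained package cannot do).
We calibrated it against the model's own phenomenology: $\epsilon$ must
be large enough that alternating 40-bin A/B blocks micro-phase separate
within desk-scale equilibration, and small enough that the chain stays
mobile rather than glassy. $\epsilon = 1\,k_BT$ is the package default
for generic runs; the mechanism fixture quenches from $1.0$ to
$1.5\,k_BT$ (see below).

**Bonded exclusion.** The LJ sum runs over $j \ge i+2$: the bonded
neighbour is excluded because the FENE term already restrains it and
$R_0 \gg 2^{1/6}\sigma$ indicates the two terms were not tuned to act
together. This is configurable (`exclude_bonded_lj`).

## Dynamics

`run_langevin()` integrates the Langevin equation with a BAOAB
splitting: deterministic velocity-Verlet steps interleaved with an exact
Ornstein-Uhlenbeck update whose noise satisfies the
fluctuation-dissipation relation. Friction is $\zeta = 0.01\,m/\tau$
(equilibrium averages do not depend on it), the main time step
$10^{-2}\,\tau$, mass 1 in reduced units. The integrator uses its own
`mt19937_64` + Marsaglia-polar normal generator so that trajectories
are bit-reproducible for a given seed across platforms.

The *push-off* phase that precedes dynamics is a capped steepest
descent on a soft force field (FENE + WCA repulsion + loop springs):
each iteration moves beads by force times a mobility `dt_soft`,
truncated at `max_move_soft` per bead. Quasi-static relaxation matters
here because the stiff loop springs must reel anchors that start many
$\sigma$ apart through the connected chain; an inertial integrator
accumulates momentum and overstretches bonds, whereas descent
distributes the strain and keeps every bond inside the FENE domain. The
descent mobility default is $10^{-4}$ (a smaller nominal step would
make the push-off a no-op at desk-scale iteration counts).

Numerical guards: a bond reaching $R_0$ or a non-finite coordinate
aborts with the step index; the LJ force is truncated at
$r_c = 2.5\,\sigma$ with a Verlet neighbour list (skin
$0.4\,\sigma$).

**Ensembles are pooled across trajectories.** A single trajectory's
frames share long-lived chain crumples; `run_langevin_ensemble()` pools
production frames from independent replicas, which is also the honest
analogue of a cross-cell structural ensemble.

# Contact-map analytics

* `contact_map_from_ensemble()` counts structures with
  $r_{ij} < 1.75\,\sigma$ (the capture radius used throughout).
* `zscore_transform()` standardizes $\log(1 + C_{ij})$ within each
  genomic separation $s$; the $+1$ admits zero counts. Diagonals with
  zero spread map to zero.
* `pearson_map()` correlates the standardized interaction profiles of
  locus pairs; `pc1_compartments()` extracts the first principal
  component and orients it so A loci are positive when a state track is
  supplied.
* `kl_divergence()` compares two samples of correlation coefficients on
  50 equal bins over $[-1, 1]$ with a pseudo-count of one per bin
  (natural log). The binning is a pinned convention: the divergence is
  reported on this fixed discretization.
* `contacts_to_distances()` / `distances_to_contacts()` apply the
  empirical power law $P_{ij} \propto R_{ij}^{-4.1}$. The
  proportionality constant is anchored by setting the mean
  nearest-neighbour distance to one bead diameter; zero contacts are
  replaced by half the smallest positive entry before inversion.
* `ward_linkage_matrix()` clusters loci by Ward's criterion
  (`hclust(method = "ward.D2")`) on a spatial distance map and returns
  the cophenetic merge-height matrix; `compare_wlm()` is the Pearson
  correlation of upper triangles. The cophenetic reading of the
  linkage matrix is a pinned choice; it is ultrametric by construction,
  which the tests exploit.

# TAD calling and P-TAD classification

`binsignal()` is the mean contact frequency between the upstream
$w$-bin window and the downstream $w$-bin window at each bin (default
$w = 5$), truncated at chromosome ends; missing bins (rows whose
contact frequencies sum to zero) are excluded from the means.

`call_tads()` takes candidates at windowed local minima of the
binSignal (minimum within $\pm w$, leftmost tie-break) and filters
false detections with a Wilcoxon rank-sum test. The exact rank-sum
construction is pinned as follows, because the published outline leaves
it open:

* the samples are the *distance-standardized* z-values of the
  cross-boundary diamond versus the two flanking within-window
  triangles. Raw counts would be biased: the diamond spans larger
  genomic separations than the triangles, so under the ubiquitous
  $P(s)$ decay every candidate would look depleted;
* the test is two-sided at level $\alpha = 0.05$ and the diamond median
  must lie below the flank median;
* because each candidate was already selected as the minimum of
  $2w + 1$ overlapping window positions, the per-candidate threshold is
  $\alpha/(2w+1)$ — without this selection correction a
  diagonal-shuffled null map yields a non-trivial boundary count.

Domains are the half-open intervals between successive boundaries. The
`missing_bin_filter()` keeps a domain only if each boundary has at most
one missing bin within 250 kb.

`match_ptads()` implements the preservation rule: a wild-type TAD is
preserved iff a depleted TAD has both boundaries within one bin (50 kb)
and reciprocal overlap at least 80% (intersection over each interval's
length; the reciprocal reading is the stricter of the two possible ones
and is configurable). Multiple eligible matches are resolved greedily
by descending overlap, one depleted TAD per wild-type TAD.

The epigenetic-switch classifier applies three filters: (I) a switch
must span at least two bins on each side (`detect_switches()`); (II) it
must lie strictly closer than 100 kb to a P-TAD boundary; (III) the two
TADs flanking that boundary must each be at least 70% one state.
Records failing II are `no-switch`; records failing III are
`filtered`.

# Boundary strengths and probabilities

For a single structure's distance matrix, the strength windows at locus
$i$ are pinned as: left columns $i-3, i-2, i-1$ and right columns
$i, i+1, i+2$, each contributing its six entries immediately below
(for L and R) or above (for T and B) the diagonal. The start-of-domain
strength is L/R and the end-of-domain strength is B/T; with this
convention *both* peak at the first locus of the downstream domain, so
start- and end-boundary probabilities reinforce at the same junction
bin. The prose description of these windows admits several indexings;
this one was selected because it is validated behaviourally: on
constructed two-cluster geometries the argmax of both strengths sits
exactly at the implanted junction.

Per structure, boundary loci are local maxima (within $\pm 2$ bins,
leftmost tie-break) of each strength above a threshold of 1.2 (the
acceptance properties are robust across roughly 1.1-1.4; the value is
configurable). Boundary probabilities are the fraction of structures in
which a locus is a boundary; the mean of start- and end-probabilities
is the boundary probability. `preferred_boundaries()` standardizes the
profile over the analysis region and keeps local maxima with Z-score
above 0.7. A P-TAD is `physical-boundary` supported when both of its
boundaries coincide (within one bin) with preferred boundaries in both
conditions.

`dbscan_clusters()` is a classic DBSCAN over the A loci and B loci
separately, with `MinPoints = 6` from the $2 \times D$ rule at spatial
dimension $D = 3$; `kdistance_elbow()` supplies the radius from the
maximum-curvature point of the sorted 6-distance curve. No installed R
package provides DBSCAN, so the implementation is first-party and is
tested against an independent quadratic-time reference.

# Maximum-entropy structures from a contact map

`hipps_structures()` goes from a contact map to a 3D ensemble without
polymer simulation: contacts are converted to target mean distances by
the 4.1 power law, and a Gaussian-form maximum-entropy model
$P(\{x\}) \propto \exp(-\sum_{i<j} k_{ij} r_{ij}^2)$ is fitted so its
mean distances match the targets. The quadratic form keeps everything
closed-form: per Cartesian dimension the coordinates are multivariate
normal with precision twice the coupling Laplacian (centre of mass
projected out), and mean distances follow from the Gaussian identity
$\langle r \rangle = \sqrt{8/(3\pi)}\sqrt{\langle r^2 \rangle}$.

Couplings update multiplicatively,
$k_{ij} \leftarrow k_{ij}(\langle r^2_{ij}\rangle / r^{2,target}_{ij})^{\eta}$
with $\eta = 0.5$; backbone couplings are floored at a small positive
value so the model remains a proper connected chain, and other
couplings stay non-negative — a pair that "wants" to be farther than
the rest of the network allows simply relaxes toward zero coupling.
Convergence requires both the median per-pair relative error below
`tol` (default 1%) and the 99th percentile below `5 * tol`, so a few
stray pairs cannot hide behind a good median. Non-convergence is
reported with the worst pairs rather than silently accepted.

`calibrate_contact_threshold()` scans capture radii (0.5-3.0 times the
ensemble's mean nearest-neighbour distance, step 0.05), recomputes the
contact map at each, and keeps the radius maximizing the Pearson
correlation of log maps with the reference, breaking ties by total
contact density. On self-generated references it recovers the
generating radius to within one grid step.

# Synthetic data: what it emulates and what it does not

`make_block_contact_map()` builds the statistical structure the
analysis stages assume Hi-C to have: power-law decay
$P(s) \propto s^{-\gamma}$ (default $\gamma = 1$), TAD squares
(multiplicative enrichment, default 3-fold), a same-state compartment
checkerboard, independent Poisson count noise, and missing bins
synthesized by zeroing a row and column. `make_boundary_ensemble()`
produces two compact clusters with a sharp junction: deterministic
line-segment backbones (spacing 0.3 sigma) separated by 10 sigma, plus
per-locus Gaussian jitter, so the jitter-to-zero limit has bit-stable
geometry and known boundary ground truth. Cell-to-cell boundary
variability is emulated by drawing each structure's junction from a
set of candidates.

These generators deliberately omit: read-level artefacts (ligation
noise, duplicates, balancing), distance-dependent noise correlations,
nested/hierarchical TADs, and sequence-dependent loop placement.
Passing tests on them therefore demonstrates the correctness of the
algorithms under the stated statistical model, not performance on real
Hi-C, where normalization and caller-parameter sensitivity dominate.

# The desk-scale mechanism fixture

`ccm_mechanism_fixture()` freezes the study conditions for the
loop-deletion mechanism: 200 loci in five alternating 40-bin A/B
blocks; a loop-only domain [11, 31) held by nested anchors
(11-30, 11-20, 20-30) inside the first, epigenetically homogeneous A
block; a corner loop (121-160) on the switch-bounded fourth block. Thirty
independent trajectories per condition are annealed — 40k steps at
$\epsilon = 1.0$, then 40k at $\epsilon = 1.5$, then 40k production
steps sampled every 500 — and pooled (2400 structures per condition).
Two properties of desk-scale copolymer sampling dictate this layout.
Annealing: a direct quench to the working $\epsilon$ traps chain
crumples formed during collapse, which masquerade as domains in the
pooled map. Replication: crumples are frozen *per trajectory*, so their
spurious insulation dips average down like $1/n_{traj}$ in the pooled
map, while the A/B-interface dips — common to every replica — do not;
at 30 replicas the interface signal dominates. TADs are called on both
maps, matched by
the P-TAD rule, classified by switch, and DBSCAN A-cluster counts are
compared using a single radius chosen from the wild-type k-distance
elbow (the same radius for both conditions, so counts are comparable).

Problem sizes throughout the test suite and the acceptance script
(N = 200 loci, 1.5e5 steps per trajectory, hundreds rather than
thousands of maximum-entropy structures) are the package's desk-scale
defaults; the same functions accept paper-scale arguments (N ~ 2000,
1e8 steps, 10,000 structures) for cluster runs.

# Known limitations

* The copolymer runs are far shorter than production simulations; at
  these lengths boundary positions in simulated maps carry ±1-2 bin
  sampling scatter, which is why the mechanism assertions are stated
  at the TAD level (a switch-bounded TAD is preserved; the loop-only
  TAD is lost) rather than demanding every interface be recovered.
* The maximum-entropy model constrains second moments with non-negative
  couplings; targets that are not realizable by any Gaussian chain
  (e.g. exact distances of a single rigid conformation) are matched
  only in the median sense, and the fit reports its worst pairs.
* The TAD caller pins several conventions the upstream description
  leaves open (rank-sum samples, selection correction, tie-breaks);
  they are documented above and validated by recovery/specificity
  properties, but they are conventions, and numbers such as domain
  counts shift with them, as they do across published callers.
* cooler/HDF5 input is not supported (no HDF5 reader in the supported
  dependency set); dense text with a JSON sidecar is the interchange
  format.
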
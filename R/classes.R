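## Light S3 containers shared across the package.
##
## Conventions (used everywhere, converted only at I/O boundaries):
##  * bins are 1-based; intervals are half-open [start, end) in bin units;
##  * a boundary "position" is the start bin of the downstream domain;
##  * genomic bp of bin b start = (b - 1) * resolution_bp.

#' Chromosome specification for the copolymer model
#'
#' Bundles the per-locus epigenetic states (A = active/euchromatin,
#' B = repressive/heterochromatin), the bin resolution, the CTCF/cohesin
#' loop-anchor pairs and the loop occupancy probability `PL`. `PL = 1`
#' restrains every anchor pair (wild type); `PL = 0` restrains none
#' (cohesin depleted); intermediate values restrain each pair independently
#' with probability `PL`.
#'
#' @param states character vector of per-locus labels, each "A" or "B".
#' @param resolution_bp base pairs per locus (bin). Default 50000.
#' @param loop_anchors integer matrix with two columns (p, q), 1-based locus
#'   indices, p < q (rows are normalized if given reversed). May have 0 rows.
#' @param pl loop occupancy probability in \[0, 1\].
#' @return An object of class `chromosome_spec`.
#' @export
chromosome_spec <- function(states, resolution_bp = 50000L,
                            loop_anchors = matrix(integer(), ncol = 2),
                            pl = 1) {
  states <- as.character(states)
  if (!length(states) || !all(states %in% c("A", "B")))
    stop("states must be a non-empty vector of 'A'/'B' labels")
  loop_anchors <- matrix(as.integer(loop_anchors), ncol = 2)
  if (nrow(loop_anchors)) {
    flip <- loop_anchors[, 1] > loop_anchors[, 2]
    loop_anchors[flip, ] <- loop_anchors[flip, 2:1]
    if (any(loop_anchors[, 1] == loop_anchors[, 2]))
      stop("loop anchors must have p < q")
    if (any(loop_anchors < 1L) || any(loop_anchors > length(states)))
      stop("loop anchor indices out of range")
  }
  if (pl < 0 || pl > 1) stop("pl must be in [0, 1]")
  structure(list(n_loci = length(states), states = states,
                 resolution_bp = as.integer(resolution_bp),
                 loop_anchors = loop_anchors, pl = pl),
            class = "chromosome_spec")
}

#' @export
print.chromosome_spec <- function(x, ...) {
  cat(sprintf("chromosome_spec: %d loci @ %d bp (%d A / %d B), %d loop anchors, PL = %g\n",
              x$n_loci, x$resolution_bp, sum(x$states == "A"),
              sum(x$states == "B"), nrow(x$loop_anchors), x$pl))
  invisible(x)
}

#' Contact map container
#'
#' @param C symmetric non-negative numeric matrix of contact counts or
#'   frequencies.
#' @param resolution_bp bin size in bp.
#' @param offset_bp genomic coordinate of the start of bin 1.
#' @param chrom chromosome name carried through I/O.
#' @return object of class `contact_map`; `$mask` flags missing bins
#'   (rows whose contact frequencies sum to zero).
#' @export
contact_map <- function(C, resolution_bp = 50000L, offset_bp = 0,
                        chrom = "chrS") {
  C <- as.matrix(C)
  dimnames(C) <- NULL
  if (nrow(C) != ncol(C)) stop("contact map must be square")
  if (any(!is.finite(C))) stop("contact map has non-finite entries")
  if (max(abs(C - t(C))) > 1e-8 * max(1, max(abs(C))))
    stop("contact map must be symmetric")
  C <- (C + t(C)) / 2
  if (any(C < 0)) stop("contact map must be non-negative")
  structure(list(C = C, n_bins = nrow(C),
                 resolution_bp = as.integer(resolution_bp),
                 offset_bp = offset_bp, chrom = chrom,
                 mask = rowSums(C) == 0),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map: %d x %d bins @ %d bp (%s), %d missing bins\n",
              x$n_bins, x$n_bins, x$resolution_bp, x$chrom, sum(x$mask)))
  invisible(x)
}

#' Distance map container
#'
#' Symmetric matrix of mean pairwise 3D distances, zero diagonal, in units
#' of the bead diameter sigma (or relative units when converted from
#' contacts).
#'
#' @param R symmetric positive (off-diagonal) matrix.
#' @param provenance "measured" (from structures) or "converted" (from a
#'   contact map via the power law).
#' @inheritParams contact_map
#' @export
distance_map <- function(R, resolution_bp = 50000L, offset_bp = 0,
                         provenance = c("measured", "converted")) {
  R <- as.matrix(R)
  dimnames(R) <- NULL
  if (nrow(R) != ncol(R)) stop("distance map must be square")
  if (max(abs(R - t(R))) > 1e-8 * max(1, max(abs(R))))
    stop("distance map must be symmetric")
  R <- (R + t(R)) / 2
  diag(R) <- 0
  if (any(R[row(R) != col(R)] < 0)) stop("distances must be non-negative")
  structure(list(R = R, n_bins = nrow(R),
                 resolution_bp = as.integer(resolution_bp),
                 offset_bp = offset_bp,
                 provenance = match.arg(provenance)),
            class = "distance_map")
}

#' Ensemble of 3D conformations
#'
#' @param coords numeric array structures x loci x 3, coordinates in sigma.
#' @param spec optional `chromosome_spec` the structures realize.
#' @param provenance free-form list recording how the ensemble was produced.
#' @export
ensemble <- function(coords, spec = NULL, provenance = list()) {
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3)
    stop("coords must be a structures x loci x 3 array")
  if (any(!is.finite(coords))) stop("non-finite coordinates")
  if (!is.null(spec) && dim(coords)[2] != spec$n_loci)
    stop("locus count does not match spec")
  structure(list(coords = coords, n_structures = dim(coords)[1],
                 n_loci = dim(coords)[2], spec = spec,
                 provenance = provenance),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("ensemble: %d structures x %d loci\n",
              x$n_structures, x$n_loci))
  invisible(x)
}

#' Extract one structure from an ensemble as an N x 3 matrix
#' @param ens an `ensemble`.
#' @param i structure index.
#' @export
ensemble_structure <- function(ens, i) {
  matrix(ens$coords[i, , ], ncol = 3)
}

#' TAD set container
#'
#' @param intervals integer matrix with columns `start`, `end`: sorted,
#'   non-overlapping half-open bin intervals.
#' @param n_bins extent of the underlying matrix.
#' @param condition label, e.g. "WT" or "depleted".
#' @param binsignal optional per-bin insulation values.
#' @param params list of caller parameters for provenance.
#' @export
tad_set <- function(intervals, n_bins, condition = "WT",
                    binsignal = NULL, params = list()) {
  intervals <- matrix(as.integer(intervals), ncol = 2,
                      dimnames = list(NULL, c("start", "end")))
  if (nrow(intervals)) {
    o <- order(intervals[, 1])
    intervals <- intervals[o, , drop = FALSE]
    if (any(intervals[, 2] <= intervals[, 1]))
      stop("intervals must satisfy start < end")
    if (any(intervals[, 1] < 1L) || any(intervals[, 2] > n_bins + 1L))
      stop("intervals outside the matrix")
    if (nrow(intervals) > 1 &&
        any(intervals[-1, 1] < intervals[-nrow(intervals), 2]))
      stop("intervals overlap")
  }
  structure(list(intervals = intervals, n_bins = as.integer(n_bins),
                 condition = condition, binsignal = binsignal,
                 params = params),
            class = "tad_set")
}

#' @export
print.tad_set <- function(x, ...) {
  cat(sprintf("tad_set (%s): %d domains over %d bins\n",
              x$condition, nrow(x$intervals), x$n_bins))
  invisible(x)
}
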
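## TopDom-style TAD calling, the missing-bin filter, preserved-TAD (P-TAD)
## matching between conditions, and the epigenetic-switch classifier.
##
## A boundary is the start bin of the downstream domain; domains are
## half-open [start, end) bin intervals. The caller follows the published
## TopDom outline: per-bin insulation ("binSignal") as the mean contact
## frequency between the upstream and downstream w-bin windows, boundaries
## at local minima, then a Wilcoxon rank-sum filter comparing the
## cross-boundary diamond against the flanking within-domain contacts. The
## exact rank-sum sample construction is pinned here (diamond vs the union
## of the two flanking within-window triangles); the published tool's
## source is the ultimate arbiter of that detail, and the choice is
## configurable in the sense that alpha and w are.

#' Per-bin insulation signal (binSignal)
#'
#' `binsignal(i)` is the mean contact frequency over the w x w rectangle
#' between the upstream bins (i-w+1 .. i) and the downstream bins
#' (i+1 .. i+w), truncated at the chromosome ends. Missing bins (mask) are
#' excluded from the mean. Bin i = n has no downstream window and gets NA.
#'
#' @param cm a [contact_map()] or symmetric matrix.
#' @param w window half-width in bins (>= 1).
#' @return numeric vector of length n (signal at bins 1 .. n).
#' @export
binsignal <- function(cm, w = 5L) {
  C <- if (inherits(cm, "contact_map")) cm$C else as.matrix(cm)
  mask <- if (inherits(cm, "contact_map")) cm$mask else rowSums(C) == 0
  if (w < 1) stop("w must be >= 1")
  n <- nrow(C)
  Cna <- C
  Cna[mask, ] <- NA
  Cna[, mask] <- NA
  out <- rep(NA_real_, n)
  for (i in seq_len(n - 1)) {
    up <- max(1L, i - w + 1L):i
    dn <- (i + 1L):min(n, i + w)
    out[i] <- mean(Cna[up, dn, drop = FALSE], na.rm = TRUE)
  }
  out[is.nan(out)] <- NA
  out
}

# windowed local minima: bin i qualifies iff its signal is the minimum of
# the +/- w neighbourhood and strictly below at least one neighbour on each
# side of the window; plateaus resolve to the leftmost bin. NA entries never
# qualify and are ignored inside windows.
.local_minima <- function(s, w = 2L) {
  n <- length(s)
  out <- logical(n)
  for (i in seq_len(n)) {
    if (!is.finite(s[i])) next
    win <- max(1L, i - w):min(n, i + w)
    v <- s[win]
    if (any(is.finite(v) & v < s[i])) next
    ties <- win[is.finite(s[win]) & s[win] == s[i]]
    if (min(ties) < i) next  # leftmost of the plateau
    left <- s[max(1L, i - w):max(1L, i - 1L)]
    right <- s[min(n, i + 1L):min(n, i + w)]
    if (i > 1 && !any(is.finite(left) & left > s[i])) next
    if (i < n && !any(is.finite(right) & right > s[i])) next
    out[i] <- TRUE
  }
  out
}

#' Call TADs from a contact map (TopDom-style)
#'
#' Candidate boundaries are windowed local minima of the [binsignal()]
#' (minimum within +/- w bins). False detections are filtered with a
#' Wilcoxon rank-sum test of the cross-boundary diamond (contacts between
#' the upstream and downstream w-windows) against the flanking
#' within-window contacts. The rank-sum construction pinned here (the
#' published outline leaves it open; see the module notes):
#' the samples are distance-standardized log-scale values
#' ([zscore_transform()]) rather than raw counts, which removes the
#' genomic-distance decay that would otherwise make every diamond look
#' depleted relative to its flanks; the test is two-sided at level
#' `alpha` with the diamond median required to lie below the flank
#' median; and because a candidate is already selected as the minimum of
#' 2w+1 overlapping window positions, the threshold is
#' selection-corrected to `alpha / (2w + 1)`. Domains are the half-open
#' intervals between successive boundaries, including the two
#' chromosome-end segments. An all-missing matrix yields an empty set.
#'
#' @param cm a [contact_map()] or matrix.
#' @param w TopDom window parameter (default 5).
#' @param alpha rank-sum significance level (default 0.05), applied as
#'   `alpha / (2w + 1)` per candidate.
#' @param condition label stored on the result.
#' @return a [tad_set()].
#' @export
call_tads <- function(cm, w = 5L, alpha = 0.05, condition = "WT") {
  C <- if (inherits(cm, "contact_map")) cm$C else as.matrix(cm)
  mask <- if (inherits(cm, "contact_map")) cm$mask else rowSums(C) == 0
  n <- nrow(C)
  bs <- binsignal(cm, w)
  if (all(!is.finite(bs)))
    return(tad_set(matrix(integer(), ncol = 2), n, condition,
                   binsignal = bs, params = list(w = w, alpha = alpha)))
  cand <- which(.local_minima(bs, w))
  keep <- logical(length(cand))
  Z <- zscore_transform(cm)
  Z[mask, ] <- NA
  Z[, mask] <- NA
  for (k in seq_along(cand)) {
    i <- cand[k]
    up <- max(1L, i - w + 1L):i
    dn <- (i + 1L):min(n, i + w)
    diamond <- as.vector(Z[up, dn])
    flank_up <- Z[up, up][upper.tri(diag(length(up)))]
    flank_dn <- Z[dn, dn][upper.tri(diag(length(dn)))]
    flank <- c(flank_up, flank_dn)
    diamond <- diamond[is.finite(diamond)]
    flank <- flank[is.finite(flank)]
    if (length(diamond) < 2 || length(flank) < 2) next
    p <- suppressWarnings(
      wilcox.test(diamond, flank, alternative = "two.sided")$p.value)
    keep[k] <- is.finite(p) && p < alpha / (2 * w + 1) &&
      median(diamond) < median(flank)
  }
  # boundary = start of the downstream domain = minimum bin + 1
  bnd <- cand[keep] + 1L
  bnd <- bnd[bnd > 1L & bnd <= n]
  iv <- if (length(bnd)) {
    edges <- unique(c(1L, bnd, n + 1L))
    cbind(start = edges[-length(edges)], end = edges[-1])
  } else matrix(integer(), ncol = 2)
  tad_set(iv, n, condition, binsignal = bs,
          params = list(w = w, alpha = alpha))
}

#' Missing-bin filter on a TAD set
#'
#' Keeps a domain only if each of its two boundaries has at most one
#' missing bin within 250 kb (5 bins at 50-kb resolution, i.e. the
#' boundary bin and the `range_bins` bins on each side are inspected over
#' a window of `2*range_bins + 1` bins centred on the boundary).
#'
#' @param tads a [tad_set()].
#' @param cm the [contact_map()] supplying the missing-bin mask.
#' @param range_bp window half-width in bp (default 250 kb).
#' @param max_missing maximum missing bins tolerated per boundary window.
#' @return filtered [tad_set()].
#' @export
missing_bin_filter <- function(tads, cm, range_bp = 250000,
                               max_missing = 1L) {
  mask <- if (inherits(cm, "contact_map")) cm$mask else
    rowSums(as.matrix(cm)) == 0
  res <- if (inherits(cm, "contact_map")) cm$resolution_bp else 50000L
  rb <- as.integer(round(range_bp / res))
  n <- tads$n_bins
  count_near <- function(b) {
    win <- max(1L, b - rb):min(n, b + rb)
    sum(mask[win])
  }
  if (!nrow(tads$intervals)) return(tads)
  ok <- vapply(seq_len(nrow(tads$intervals)), function(k) {
    st <- tads$intervals[k, 1]
    en <- tads$intervals[k, 2]
    count_near(st) <= max_missing && count_near(min(en, n)) <= max_missing
  }, logical(1))
  tad_set(tads$intervals[ok, , drop = FALSE], n, tads$condition,
          binsignal = tads$binsignal,
          params = c(tads$params, list(missing_filter_bp = range_bp)))
}

#' Match wild-type TADs to cohesin-depleted TADs (P-TAD rule)
#'
#' A WT TAD is preserved iff some depleted TAD has both boundaries within
#' `window_bins` (default 1 bin = 50 kb) of the corresponding WT
#' boundaries and the reciprocal overlap is at least `min_overlap`
#' (intersection over *each* interval's length, default 0.8; set
#' `reciprocal = FALSE` for the WT-sided reading). Each depleted TAD is
#' used at most once: candidates are assigned greedily by descending
#' overlap fraction.
#'
#' @param wt,dep [tad_set()] objects at the same resolution.
#' @param window_bins boundary tolerance in bins.
#' @param min_overlap minimum overlap fraction.
#' @param reciprocal require the overlap fraction on both lengths.
#' @return data.frame with one row per WT TAD: `wt_start`, `wt_end`,
#'   `dep_start`, `dep_end` (NA when unmatched), `start_offset`,
#'   `end_offset`, `overlap`, and `preserved`.
#' @export
match_ptads <- function(wt, dep, window_bins = 1L, min_overlap = 0.8,
                        reciprocal = TRUE) {
  wi <- wt$intervals
  di <- dep$intervals
  nw <- nrow(wi)
  out <- data.frame(wt_start = wi[, 1], wt_end = wi[, 2],
                    dep_start = NA_integer_, dep_end = NA_integer_,
                    start_offset = NA_integer_, end_offset = NA_integer_,
                    overlap = NA_real_,
                    preserved = rep(FALSE, nw))
  if (!nw || !nrow(di)) return(out)
  # candidate pairs via IRanges overlap, then filtered by the boundary rule
  wr <- IRanges::IRanges(start = wi[, 1], end = wi[, 2] - 1L)
  dr <- IRanges::IRanges(start = di[, 1], end = di[, 2] - 1L)
  hits <- IRanges::findOverlaps(wr, dr)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  if (!length(qh)) return(out)
  inter <- pmin(wi[qh, 2], di[sh, 2]) - pmax(wi[qh, 1], di[sh, 1])
  frac_w <- inter / (wi[qh, 2] - wi[qh, 1])
  frac_d <- inter / (di[sh, 2] - di[sh, 1])
  frac <- if (reciprocal) pmin(frac_w, frac_d) else frac_w
  so <- di[sh, 1] - wi[qh, 1]
  eo <- di[sh, 2] - wi[qh, 2]
  elig <- abs(so) <= window_bins & abs(eo) <= window_bins &
    frac >= min_overlap
  ord <- order(-frac, qh, sh)
  used_w <- logical(nw)
  used_d <- logical(nrow(di))
  for (r in ord[elig[ord]]) {
    q <- qh[r]; s <- sh[r]
    if (used_w[q] || used_d[s]) next
    used_w[q] <- TRUE
    used_d[s] <- TRUE
    out$dep_start[q] <- di[s, 1]
    out$dep_end[q] <- di[s, 2]
    out$start_offset[q] <- so[r]
    out$end_offset[q] <- eo[r]
    out$overlap[q] <- frac[r]
    out$preserved[q] <- TRUE
  }
  out
}

#' Detect epigenetic switches in an A/B state track
#'
#' A switch is a position where the state changes and *both* flanking runs
#' span at least `min_run` bins (filter I: switches occupying only one
#' 50-kb locus are excluded). Returns the first bin of the downstream run.
#'
#' @param states per-bin "A"/"B" labels.
#' @param min_run minimum run length on each side (default 2 bins).
#' @return integer vector of switch positions (bins).
#' @export
detect_switches <- function(states, min_run = 2L) {
  r <- rle(as.character(states))
  k <- length(r$lengths)
  if (k < 2) return(integer())
  starts <- cumsum(c(1L, r$lengths[-k]))
  ok <- r$lengths[-k] >= min_run & r$lengths[-1] >= min_run
  starts[-1][ok]
}

#' Classify P-TADs by epigenetic switch (filters I-III)
#'
#' Annotates [match_ptads()] records: a preserved TAD is switch-associated
#' iff (II) a filtered switch (see [detect_switches()], filter I) lies
#' strictly closer than `max_gap_bp` to one of its boundaries, and (III)
#' the two TADs flanking that boundary each consist of at least `purity`
#' fraction of a single epigenetic state. Non-preserved records are
#' labelled "not-preserved".
#'
#' @param ptads data.frame from [match_ptads()].
#' @param switches switch positions from [detect_switches()] (bins).
#' @param states per-bin A/B labels (for the purity filter).
#' @param resolution_bp bin size.
#' @param max_gap_bp maximum boundary-to-switch distance (strict, bp).
#' @param purity minimum single-state fraction in each flanking TAD.
#' @return `ptads` with columns `switch_status`
#'   (switch-preserved / no-switch / filtered / not-preserved),
#'   `switch_boundary` (the matched boundary bin or NA).
#' @export
classify_switch_ptads <- function(ptads, switches, states,
                                  resolution_bp = 50000,
                                  max_gap_bp = 100000, purity = 0.70) {
  n <- length(states)
  bp <- function(b) (b - 1) * resolution_bp
  tad_edges <- sort(unique(c(ptads$wt_start, ptads$wt_end)))
  purity_of <- function(lo, hi) {  # [lo, hi) in bins
    if (hi <= lo) return(NA_real_)
    seg <- states[lo:(hi - 1)]
    max(mean(seg == "A"), mean(seg == "B"))
  }
  flank_pure <- function(b) {
    # intervals left and right of boundary b, taken from the WT TAD edges
    left_lo <- max(c(1L, tad_edges[tad_edges < b]))
    right_hi <- min(c(n + 1L, tad_edges[tad_edges > b]))
    pl <- purity_of(left_lo, b)
    pr <- purity_of(b, right_hi)
    is.finite(pl) && is.finite(pr) && pl >= purity && pr >= purity
  }
  status <- rep("not-preserved", nrow(ptads))
  sw_bnd <- rep(NA_integer_, nrow(ptads))
  for (k in seq_len(nrow(ptads))) {
    if (!ptads$preserved[k]) next
    bnds <- c(ptads$wt_start[k], ptads$wt_end[k])
    near <- NA_integer_
    for (b in bnds) {
      if (length(switches) &&
          any(abs(bp(switches) - bp(b)) < max_gap_bp)) { near <- b; break }
    }
    if (is.na(near)) { status[k] <- "no-switch"; next }
    status[k] <- if (flank_pure(near)) "switch-preserved" else "filtered"
    if (status[k] == "switch-preserved") sw_bnd[k] <- near
  }
  ptads$switch_status <- status
  ptads$switch_boundary <- sw_bnd
  ptads
}
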
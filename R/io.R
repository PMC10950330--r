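## File formats. On-disk dialects (all plain text):
##  * contact/distance maps: dense whitespace-delimited floats, no header,
##    with a JSON sidecar <path>.json holding resolution_bp, offset_bp,
##    chrom;
##  * A/B state tracks: 4-column BED (chrom, start, end, A|B), 0-based
##    half-open bp;
##  * loop anchors: 6-column BEDPE (chrom1, start1, end1, chrom2, start2,
##    end2), anchors snapped to the bin containing the interval midpoint;
##  * ensembles: multi-frame XYZ (count line, comment line, "<label> x y z"
##    rows).
## Bin <-> bp conversion happens only here: bin b covers
## [offset + (b-1)*res, offset + b*res).

.sidecar_path <- function(path) paste0(path, ".json")

#' Write a contact map as dense text plus JSON sidecar
#'
#' @param cm a [contact_map()].
#' @param path output file; metadata goes to `<path>.json`.
#' @export
write_contact_matrix <- function(cm, path) {
  write.table(format(cm$C, digits = 17, trim = TRUE, scientific = TRUE),
              path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(resolution_bp = cm$resolution_bp,
                            offset_bp = cm$offset_bp, chrom = cm$chrom,
                            n_bins = cm$n_bins),
                       .sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' Read a dense-text contact map
#'
#' Validates squareness, symmetry and finiteness; the missing-bin mask
#' (zero-sum rows) is derived on construction. Metadata comes from the
#' JSON sidecar when present, else from the arguments.
#'
#' @param path dense whitespace-delimited matrix file.
#' @param resolution_bp,offset_bp,chrom fallbacks when no sidecar exists.
#' @return a [contact_map()].
#' @export
read_contact_matrix <- function(path, resolution_bp = 50000L,
                                offset_bp = 0, chrom = "chrS") {
  M <- as.matrix(read.table(path, header = FALSE,
                            colClasses = "numeric"))
  dimnames(M) <- NULL
  if (nrow(M) != ncol(M))
    stop(sprintf("matrix is not square: %d rows x %d cols",
                 nrow(M), ncol(M)))
  if (any(!is.finite(M))) {
    bad <- which(!is.finite(M), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite entry at row %d, col %d", bad[1], bad[2]))
  }
  asym <- abs(M - t(M)) > 1e-8 * max(1, max(abs(M)))
  if (any(asym)) {
    bad <- which(asym, arr.ind = TRUE)[1, ]
    stop(sprintf("asymmetric input at (%d, %d)", bad[1], bad[2]))
  }
  sc <- .sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc)
    resolution_bp <- meta$resolution_bp
    offset_bp <- meta$offset_bp
    chrom <- meta$chrom
  }
  contact_map(M, resolution_bp = resolution_bp, offset_bp = offset_bp,
              chrom = chrom)
}

#' Write an A/B state track as 4-column BED
#'
#' Adjacent bins in the same state are merged into one feature.
#'
#' @param states per-bin labels.
#' @param path output BED file.
#' @param resolution_bp bin size.
#' @param offset_bp genomic start of bin 1.
#' @param chrom chromosome name.
#' @export
write_state_track <- function(states, path, resolution_bp = 50000L,
                              offset_bp = 0, chrom = "chrS") {
  r <- rle(as.character(states))
  ends_bin <- cumsum(r$lengths)
  starts_bin <- ends_bin - r$lengths + 1L
  df <- data.frame(chrom = chrom,
                   start = offset_bp + (starts_bin - 1) * resolution_bp,
                   end = offset_bp + ends_bin * resolution_bp,
                   name = r$values)
  write.table(df, path, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Read an A/B state track (BED) into per-bin labels
#'
#' Features are expanded to bins at `resolution_bp`; the track must tile
#' `[offset_bp, offset_bp + n_bins*resolution_bp)` without overlap, and an
#' uncovered range is an error naming the gap.
#'
#' @param path 4-column BED file (chrom, start, end, A|B).
#' @param n_bins expected number of bins.
#' @param resolution_bp bin size.
#' @param offset_bp genomic start of bin 1.
#' @return character vector of per-bin labels.
#' @export
read_state_track <- function(path, n_bins, resolution_bp = 50000L,
                             offset_bp = 0) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "name"),
                   colClasses = c("character", "numeric", "numeric",
                                  "character"))
  df <- df[order(df$start), ]
  states <- rep(NA_character_, n_bins)
  for (k in seq_len(nrow(df))) {
    b1 <- floor((df$start[k] - offset_bp) / resolution_bp) + 1
    b2 <- ceiling((df$end[k] - offset_bp) / resolution_bp)
    b1 <- max(1, b1); b2 <- min(n_bins, b2)
    if (b2 < b1) next
    if (any(!is.na(states[b1:b2])))
      stop(sprintf("overlapping BED features near bin %d", b1))
    states[b1:b2] <- df$name[k]
  }
  if (anyNA(states)) {
    gap <- range(which(is.na(states)))
    stop(sprintf("track does not cover bins %d-%d (bp %g-%g)",
                 gap[1], gap[2], offset_bp + (gap[1] - 1) * resolution_bp,
                 offset_bp + gap[2] * resolution_bp))
  }
  states
}

#' Write loop anchors as 6-column BEDPE
#'
#' @param anchors 2-column matrix of bin-index pairs.
#' @param path output file.
#' @inheritParams write_state_track
#' @export
write_loops <- function(anchors, path, resolution_bp = 50000L,
                        offset_bp = 0, chrom = "chrS") {
  anchors <- matrix(as.integer(anchors), ncol = 2)
  df <- data.frame(chrom1 = chrom,
                   start1 = offset_bp + (anchors[, 1] - 1) * resolution_bp,
                   end1 = offset_bp + anchors[, 1] * resolution_bp,
                   chrom2 = chrom,
                   start2 = offset_bp + (anchors[, 2] - 1) * resolution_bp,
                   end2 = offset_bp + anchors[, 2] * resolution_bp)
  write.table(df, path, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Read loop anchors from BEDPE
#'
#' Each side is snapped to the bin containing its midpoint; pairs are
#' normalized to p < q; pairs with either side outside `[1, n_bins]` (or
#' degenerate p == q after snapping) are dropped with a warning count.
#'
#' @param path 6+ column BEDPE file.
#' @param n_bins matrix extent.
#' @inheritParams read_state_track
#' @return 2-column integer matrix of anchor bin pairs.
#' @export
read_loops <- function(path, n_bins, resolution_bp = 50000L,
                       offset_bp = 0) {
  df <- read.table(path, sep = "\t", header = FALSE)
  p <- floor(((df[[2]] + df[[3]]) / 2 - offset_bp) / resolution_bp) + 1
  q <- floor(((df[[5]] + df[[6]]) / 2 - offset_bp) / resolution_bp) + 1
  lo <- pmin(p, q)
  hi <- pmax(p, q)
  ok <- lo >= 1 & hi <= n_bins & lo < hi
  if (any(!ok))
    warning(sprintf("%d loop anchor pair(s) dropped (outside matrix or degenerate)",
                    sum(!ok)))
  cbind(as.integer(lo[ok]), as.integer(hi[ok]))
}

#' Write an ensemble as multi-frame XYZ
#'
#' @param ens an [ensemble()].
#' @param path output file.
#' @param digits coordinate precision.
#' @export
write_ensemble_xyz <- function(ens, path, digits = 8) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_len(ens$n_structures)) {
    xyz <- ensemble_structure(ens, m)
    writeLines(c(as.character(ens$n_loci),
                 sprintf("frame %d", m),
                 sprintf("L%d %.*g %.*g %.*g", seq_len(ens$n_loci),
                         digits, xyz[, 1], digits, xyz[, 2],
                         digits, xyz[, 3])), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ file into an ensemble
#'
#' @param path XYZ file written by [write_ensemble_xyz()] (or any
#'   conforming multi-frame XYZ with constant atom count).
#' @return an [ensemble()].
#' @export
read_ensemble_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop(sprintf("bad XYZ count line at line %d", i))
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- do.call(rbind, strsplit(trimws(block), "\\s+"))
    frames[[length(frames) + 1L]] <-
      matrix(as.numeric(parts[, 2:4]), ncol = 3)
    i <- i + 2L + n
  }
  n_loci <- nrow(frames[[1]])
  coords <- array(0, dim = c(length(frames), n_loci, 3))
  for (m in seq_along(frames)) coords[m, , ] <- frames[[m]]
  ensemble(coords)
}

#' Write a TAD set (and optional P-TAD annotations) as TSV
#'
#' Carries a provenance header (`#` lines: tool version, parameters).
#'
#' @param tads a [tad_set()].
#' @param path output file.
#' @param resolution_bp,offset_bp,chrom genomic coordinates for output.
#' @export
write_tads <- function(tads, path, resolution_bp = 50000L, offset_bp = 0,
                       chrom = "chrS") {
  iv <- tads$intervals
  hdr <- c(sprintf("# ptadsuite %s", as.character(utils::packageVersion("ptadsuite"))),
           sprintf("# condition=%s params=%s", tads$condition,
                   jsonlite::toJSON(tads$params, auto_unbox = TRUE)))
  df <- data.frame(chrom = rep(chrom, nrow(iv)),
                   start = offset_bp + (iv[, 1] - 1) * resolution_bp,
                   end = offset_bp + (iv[, 2] - 1) * resolution_bp,
                   start_bin = iv[, 1], end_bin = iv[, 2])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  suppressWarnings(write.table(df, con, sep = "\t", row.names = FALSE,
                               quote = FALSE))
  invisible(path)
}
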
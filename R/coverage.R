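# Fragment midpoints, 100-bp binned coverage, TSS metaprofiles.

# Values of a sorted integer vector falling in [lo, hi).
slice_sorted <- function(p, lo, hi) {
  idx <- findInterval(c(lo - 0.5, hi - 0.5), p)
  if (idx[2] <= idx[1]) return(p[0])
  p[(idx[1] + 1):idx[2]]
}

#' Infer fragment midpoints from mapped reads
#'
#' Every sequenced fragment is assumed to be `fragment_len` bp (190 bp by
#' default), so the fragment midpoint sits `fragment_len / 2` bp downstream of
#' the read 5' end: `start + 95` for plus-strand reads and `end - 95` for
#' minus-strand reads. Midpoints are clamped into `[0, chrom_length)`.
#'
#' @param reads data.frame with chrom, start, end, strand (0-based half-open).
#' @param chrom_info Named chromosome lengths used for clamping.
#' @param fragment_len Assumed fragment size in bp.
#' @return data.frame with columns chrom, pos.
#' @export
fragment_midpoints <- function(reads, chrom_info, fragment_len = 190) {
  half <- fragment_len %/% 2
  pos <- ifelse(reads$strand == "+", reads$start + half, reads$end - half)
  len <- chrom_info[reads$chrom]
  if (any(is.na(len))) stop("reads on chromosomes absent from chrom_info")
  pos <- pmax(0, pmin(pos, len - 1))
  data.frame(chrom = reads$chrom, pos = pos, stringsAsFactors = FALSE)
}

#' Build a midpoint sample from mapped reads
#'
#' A midpoint sample carries per-chromosome sorted fragment-midpoint positions
#' plus the total number of uniquely mapped reads; it is the input to binning,
#' interval occupancy and metaprofile computation.
#'
#' @param reads Mapped reads (see [read_bed_reads()]), or a midpoint
#'   data.frame with columns chrom, pos (then used as is).
#' @param chrom_info Named chromosome lengths.
#' @param fragment_len Assumed fragment size in bp.
#' @return Object of class `mark_sample`: list(midpoints, total, chrom_info).
#' @export
midpoint_sample <- function(reads, chrom_info, fragment_len = 190) {
  mids <- if (all(c("chrom", "pos") %in% names(reads))) {
    reads
  } else {
    fragment_midpoints(reads, chrom_info, fragment_len)
  }
  by_chrom <- lapply(stats::setNames(nm = names(chrom_info)), function(chrom) {
    sort(mids$pos[mids$chrom == chrom])
  })
  structure(list(midpoints = by_chrom, total = nrow(mids),
                 chrom_info = chrom_info),
            class = "mark_sample")
}

#' @export
print.mark_sample <- function(x, ...) {
  cat("<mark_sample>", x$total, "midpoints on", length(x$midpoints),
      "chromosome(s)\n")
  invisible(x)
}

#' Count fragment midpoints in fixed-width genomic bins
#'
#' Bin i of a chromosome covers `[i * bin_size, (i + 1) * bin_size)`, so the
#' total of all bins equals the number of midpoints.
#'
#' @param x A `mark_sample`, or a midpoint data.frame (chrom, pos).
#' @param chrom_info Named chromosome lengths (taken from the sample when
#'   omitted).
#' @param bin_size Bin width in bp (default 100).
#' @return Object of class `binned_track` with raw counts.
#' @export
bin_midpoints <- function(x, chrom_info = NULL, bin_size = 100) {
  if (inherits(x, "mark_sample")) {
    chrom_info <- chrom_info %||% x$chrom_info
    mids <- x$midpoints
    total <- x$total
  } else {
    if (is.null(chrom_info)) stop("chrom_info required")
    mids <- split(x$pos, factor(x$chrom, levels = names(chrom_info)))
    total <- nrow(x)
  }
  bins <- lapply(stats::setNames(nm = names(chrom_info)), function(chrom) {
    nb <- as.integer(ceiling(chrom_info[[chrom]] / bin_size))
    p <- mids[[chrom]]
    if (!length(p)) return(numeric(nb))
    as.numeric(tabulate(p %/% bin_size + 1L, nbins = nb))
  })
  structure(list(bins = bins, bin_size = bin_size, total_reads = total,
                 normalized = FALSE, chrom_info = chrom_info),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat("<binned_track>", length(x$bins), "chromosome(s),", x$bin_size,
      "bp bins,", x$total_reads, "reads,",
      if (x$normalized) "normalized\n" else "raw counts\n")
  invisible(x)
}

#' Depth-normalize a binned track
#'
#' Scales each bin to reads per `scale_reads` (5 million by default) mapped
#' reads: `value = raw * scale_reads / total_reads`.
#'
#' @param track Raw `binned_track`.
#' @param scale_reads Normalization constant in reads.
#' @return Normalized `binned_track`.
#' @export
normalize_track <- function(track, scale_reads = 5e6) {
  stopifnot(inherits(track, "binned_track"))
  if (track$normalized) stop("track is already normalized")
  if (is.na(track$total_reads) || track$total_reads <= 0) {
    stop("total_reads must be positive to normalize")
  }
  track$bins <- lapply(track$bins, function(v) v * scale_reads / track$total_reads)
  track$normalized <- TRUE
  track
}

#' Aggregate fragment midpoints around transcription start sites
#'
#' Counts sample midpoints in windows of `TSS +/- flank` for every transcript,
#' flipping minus-strand windows so positive offsets point downstream of
#' transcription, then divides each offset bin by the total count over all
#' windows: the returned density sums to 1. Windows from splice variants each
#' contribute independently.
#'
#' @param sample A `mark_sample`.
#' @param genes Gene table (see [read_refgene()]).
#' @param flank Half-window around the TSS in bp.
#' @param bin_size Offset resolution in bp; use 1 for per-bp profiles.
#' @return Object of class `meta_profile`: data.frame with columns position
#'   (window-left edge of each offset bin, relative to the TSS), count and
#'   density, plus attribute `n_tss`.
#' @export
tss_metaprofile <- function(sample, genes, flank = 5000, bin_size = 100) {
  stopifnot(inherits(sample, "mark_sample"), nrow(genes) >= 1)
  nb <- as.integer(2 * flank / bin_size)
  counts <- numeric(nb)
  for (chrom in unique(genes$chrom)) {
    p <- sample$midpoints[[chrom]]
    if (is.null(p) || !length(p)) next
    g <- genes[genes$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(g))) {
      # plus strand: positions [tss - flank, tss + flank), offset = pos - tss;
      # minus strand: positions (tss - flank, tss + flank], offset = tss - pos,
      # so offsets span [-flank, flank) downstream-positive on both strands.
      sel <- if (g$strand[i] == "+") {
        slice_sorted(p, g$tss[i] - flank, g$tss[i] + flank)
      } else {
        slice_sorted(p, g$tss[i] - flank + 1, g$tss[i] + flank + 1)
      }
      if (!length(sel)) next
      off <- if (g$strand[i] == "+") sel - g$tss[i] else g$tss[i] - sel
      idx <- (off + flank) %/% bin_size + 1L
      counts <- counts + tabulate(idx, nbins = nb)
    }
  }
  if (sum(counts) == 0) {
    stop("no midpoints in any TSS window: density undefined")
  }
  out <- data.frame(position = seq(-flank, flank - bin_size, by = bin_size),
                    count = counts, density = counts / sum(counts))
  attr(out, "n_tss") <- nrow(genes)
  class(out) <- c("meta_profile", "data.frame")
  out
}

#' LOWESS-smooth a metaprofile
#'
#' Locally weighted regression (the classic LOWESS smoother) applied to the
#' profile density, returning a curve of the same length. A constant input is
#' reproduced exactly and a linear ramp is fit exactly.
#'
#' @param profile A `meta_profile`, or a numeric vector of y values.
#' @param span LOWESS span (fraction of points in each local fit), in (0, 1].
#' @param positions x values when `profile` is a plain vector.
#' @return For a `meta_profile`, the profile with a `smoothed` column added;
#'   for a vector, the smoothed vector.
#' @export
lowess_smooth <- function(profile, span = 0.05, positions = NULL) {
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  if (inherits(profile, "meta_profile")) {
    if (nrow(profile) < 10) stop("need >= 10 positions to smooth")
    fit <- stats::lowess(profile$position, profile$density, f = span)
    profile$smoothed <- fit$y[order(order(profile$position))]
    return(profile)
  }
  y <- as.numeric(profile)
  if (length(y) < 10) stop("need >= 10 positions to smooth")
  x <- positions %||% seq_along(y)
  stats::lowess(x, y, f = span)$y[order(order(x))]
}

#' Locate peaks in a smoothed profile
#'
#' A peak is a local maximum whose prominence (height above the higher of the
#' two flanking minima separating it from larger peaks) exceeds
#' `min_prominence` times the curve's full range. The prominence filter makes
#' peak counting on sampled noisy curves well defined; with the default of
#' 0.2, small wiggles in flat background are ignored.
#'
#' @param position x coordinates.
#' @param y Smoothed curve values.
#' @param min_prominence Minimum prominence as a fraction of `max(y) - min(y)`.
#' @return data.frame with columns position and height, one row per peak,
#'   ordered by position.
#' @export
find_profile_peaks <- function(position, y, min_prominence = 0.2) {
  n <- length(y)
  stopifnot(length(position) == n, n >= 3)
  cand <- which(diff(sign(diff(y))) < 0) + 1L
  if (!length(cand)) return(data.frame(position = numeric(), height = numeric()))
  rng <- diff(range(y))
  if (rng == 0) return(data.frame(position = numeric(), height = numeric()))
  keep <- logical(length(cand))
  for (j in seq_along(cand)) {
    i <- cand[j]
    # walk outwards until a higher point is met; prominence is height above
    # the deeper side's minimum, taking the higher of the two side minima
    left <- y[seq_len(i - 1)]
    right <- y[seq(i + 1, n)]
    lhigher <- which(left >= y[i])
    rhigher <- which(right >= y[i])
    lmin <- if (length(lhigher)) min(left[seq(max(lhigher), length(left))]) else min(left)
    rmin <- if (length(rhigher)) min(right[seq_len(min(rhigher))]) else min(right)
    prom <- y[i] - max(lmin, rmin)
    keep[j] <- prom >= min_prominence * rng
  }
  data.frame(position = position[cand[keep]], height = y[cand[keep]])
}
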
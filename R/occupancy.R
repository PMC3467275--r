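# Normalized interval occupancy: reads per kb per 5 million mapped reads.

MARKS <- c("H3K4me2", "H3K27me3")
STAGES <- c("E17.5", "PN1", "PN7", "PN15")

# "mark:stage" column keys for occupancy matrices.
sample_key <- function(mark, stage) paste(mark, stage, sep = ":")

#' Normalized occupancy of a genomic interval
#'
#' `occupancy = reads * scale_reads * kb_constant /
#'              (total_reads * length_in_kb)`,
#' i.e. reads per kb of interval per `scale_reads` (5 million) mapped reads.
#' `kb_constant` exposes the alternative x1000 convention some software uses;
#' the default of 1 yields occupancies commensurate with a mock-control
#' background of order 10 in real datasets.
#'
#' @param reads Midpoint count in the interval (vectorized).
#' @param length_bp Interval length in bp (> 0).
#' @param total_reads Total mapped reads in the experiment (> 0).
#' @param scale_reads Depth normalization constant.
#' @param kb_constant Extra multiplier (1 or 1000).
#' @return Occupancy value(s).
#' @export
interval_occupancy <- function(reads, length_bp, total_reads,
                               scale_reads = 5e6, kb_constant = 1) {
  if (any(length_bp <= 0)) stop("interval length must be > 0")
  if (any(total_reads <= 0)) stop("total_reads must be > 0")
  reads * scale_reads * kb_constant / (total_reads * (length_bp / 1000))
}

#' Strand-aware gene intervals
#'
#' * `tss`: `[TSS - flank, TSS + flank)`
#' * `promoter`: the `flank` bp upstream of the TSS (on the minus strand this
#'   is `[TSS, TSS + flank)` in genome coordinates)
#' * `body`: TSS to TES, i.e. `[tx_start, tx_end)`
#'
#' Intervals are clipped at position 0.
#'
#' @param genes Gene table with chrom, strand, tx_start, tx_end, tss, tes.
#' @param interval Interval kind.
#' @param flank Flank size in bp (2500 by default).
#' @return data.frame with chrom, start, end (half-open).
#' @export
gene_intervals <- function(genes, interval = c("tss", "promoter", "body"),
                           flank = 2500) {
  interval <- match.arg(interval)
  res <- switch(interval,
    tss = data.frame(start = genes$tss - flank, end = genes$tss + flank),
    promoter = data.frame(
      start = ifelse(genes$strand == "+", genes$tss - flank, genes$tss),
      end = ifelse(genes$strand == "+", genes$tss, genes$tss + flank)),
    body = data.frame(start = genes$tx_start, end = genes$tx_end)
  )
  res$start <- pmax(0, res$start)
  data.frame(chrom = genes$chrom, start = res$start, end = res$end,
             stringsAsFactors = FALSE)
}

#' Count sample midpoints in intervals
#'
#' @param sample A `mark_sample`.
#' @param intervals data.frame with chrom, start, end (half-open).
#' @return Integer vector of counts, one per interval.
#' @export
count_midpoints <- function(sample, intervals) {
  stopifnot(inherits(sample, "mark_sample"))
  counts <- numeric(nrow(intervals))
  for (chrom in unique(intervals$chrom)) {
    p <- sample$midpoints[[chrom]]
    sel <- which(intervals$chrom == chrom)
    if (is.null(p) || !length(p)) next
    i1 <- findInterval(intervals$start[sel] - 0.5, p)
    i2 <- findInterval(intervals$end[sel] - 0.5, p)
    counts[sel] <- i2 - i1
  }
  counts
}

#' Occupancy of one interval kind for a set of samples
#'
#' @param samples Named list of `mark_sample` objects.
#' @param genes Gene table.
#' @param interval Interval kind (see [gene_intervals()]).
#' @param flank Flank in bp for tss/promoter intervals.
#' @param scale_reads,kb_constant Passed to [interval_occupancy()].
#' @return Matrix (genes x samples) of occupancies; rownames are transcript
#'   ids, attribute `interval_kind` records the interval.
#' @export
occupancy_matrix <- function(samples, genes, interval = "tss", flank = 2500,
                             scale_reads = 5e6, kb_constant = 1) {
  iv <- gene_intervals(genes, interval, flank)
  mat <- vapply(samples, function(s) {
    interval_occupancy(count_midpoints(s, iv), iv$end - iv$start, s$total,
                       scale_reads, kb_constant)
  }, numeric(nrow(genes)))
  mat <- matrix(mat, nrow = nrow(genes),
                dimnames = list(genes$transcript_id, names(samples)))
  attr(mat, "interval_kind") <- interval
  mat
}

#' Build the genes x (mark x stage) occupancy matrix
#'
#' Validates that one sample is present for every mark/stage combination and
#' orders columns mark-major (all stages of the first mark, then the second).
#'
#' @param samples Named list of `mark_sample` objects; names must be
#'   `"<mark>:<stage>"`.
#' @param genes Gene table.
#' @param interval,flank,scale_reads,kb_constant See [occupancy_matrix()].
#' @param marks,stages Design levels.
#' @return Occupancy matrix with `ncol = length(marks) * length(stages)`.
#' @export
build_occupancy_matrix <- function(samples, genes, interval = "tss",
                                   flank = 2500, scale_reads = 5e6,
                                   kb_constant = 1, marks = MARKS,
                                   stages = STAGES) {
  want <- as.vector(outer(stages, marks, function(s, m) sample_key(m, s)))
  missing <- setdiff(want, names(samples))
  if (length(missing)) {
    stop("missing sample(s) for: ", paste(missing, collapse = ", "))
  }
  occupancy_matrix(samples[want], genes, interval, flank, scale_reads,
                   kb_constant)
}

#' Mock-control background occupancy
#'
#' Arithmetic mean of the control (anti-GFP) occupancies over all genes and
#' stages; used as the background value `b` for classification.
#'
#' @param x Numeric vector or matrix of control occupancies.
#' @return Scalar background value.
#' @export
gfp_background <- function(x) {
  x <- as.numeric(x)
  if (!length(x)) stop("no control occupancies")
  mean(x)
}

#' Euclidean no-mark cutoff
#'
#' A gene whose occupancies are all at background `b` in `dims` dimensions
#' sits at Euclidean distance `sqrt(dims) * b` from the origin; that distance
#' is the cutoff below which a gene is called unmarked. With `b = 9.12` and 8
#' dimensions the cutoff is 25.80 (2 dp).
#'
#' @param b Background occupancy (>= 0).
#' @param dims Number of matrix columns (default 8: 2 marks x 4 stages).
#' @return Cutoff value.
#' @export
no_mark_cutoff <- function(b, dims = 8) {
  if (b < 0) stop("background must be >= 0")
  sqrt(dims) * b
}

#' Flag genes with no accumulation of either mark
#'
#' A gene is flagged when the Euclidean norm of its occupancy row is strictly
#' below the cutoff.
#'
#' @param mat Occupancy matrix (genes x mark-stage columns).
#' @param cutoff Cutoff from [no_mark_cutoff()].
#' @return Named logical vector.
#' @export
classify_no_mark <- function(mat, cutoff) {
  stats::setNames(sqrt(rowSums(mat^2)) < cutoff, rownames(mat))
}

#' Genome-background occupancy of one sample
#'
#' Estimates the sample's background midpoint rate from the genome outside
#' gene territories (genes extended by `exclude_flank`) and converts it to
#' occupancy units (reads per kb per `scale_reads` mapped reads). Dividing a
#' sample's occupancies by this value removes the library-composition factor
#' (the share of reads absorbed by enriched regions), which otherwise
#' confounds comparisons between libraries with different signal content.
#'
#' @param sample A `mark_sample`.
#' @param genes Gene table whose territories are excluded.
#' @param exclude_flank Extension of each gene territory in bp.
#' @param scale_reads Depth normalization constant.
#' @return Background occupancy (same units as [interval_occupancy()]).
#' @export
sample_background_occupancy <- function(sample, genes, exclude_flank = 5000,
                                        scale_reads = 5e6) {
  info <- sample$chrom_info
  outside_bp <- 0
  outside_count <- 0
  for (chrom in names(info)) {
    g <- genes[genes$chrom == chrom, , drop = FALSE]
    # merged excluded intervals
    if (nrow(g)) {
      iv <- data.frame(start = pmax(0, pmin(g$tx_start, g$tss) - exclude_flank),
                       end = pmin(info[[chrom]], pmax(g$tx_end, g$tss) + exclude_flank))
      iv <- iv[order(iv$start), , drop = FALSE]
      merged <- list()
      cs <- iv$start[1]; ce <- iv$end[1]
      for (i in seq_len(nrow(iv))[-1]) {
        if (iv$start[i] <= ce) ce <- max(ce, iv$end[i])
        else { merged[[length(merged) + 1]] <- c(cs, ce); cs <- iv$start[i]; ce <- iv$end[i] }
      }
      merged[[length(merged) + 1]] <- c(cs, ce)
      excl <- do.call(rbind, merged)
    } else {
      excl <- matrix(numeric(0), ncol = 2)
    }
    p <- sample$midpoints[[chrom]]
    n_in <- 0
    bp_in <- 0
    if (nrow(excl)) {
      bp_in <- sum(excl[, 2] - excl[, 1])
      if (length(p)) {
        i1 <- findInterval(excl[, 1] - 0.5, p)
        i2 <- findInterval(excl[, 2] - 0.5, p)
        n_in <- sum(i2 - i1)
      }
    }
    outside_bp <- outside_bp + info[[chrom]] - bp_in
    outside_count <- outside_count + length(p) - n_in
  }
  if (outside_bp <= 0) stop("no genome left outside gene territories")
  interval_occupancy(outside_count, outside_bp, sample$total, scale_reads)
}

#' Express occupancies relative to per-sample background
#'
#' @param mat Occupancy matrix.
#' @param backgrounds Background occupancy per column (named or positional),
#'   from [sample_background_occupancy()].
#' @return Matrix of background-relative occupancies (1 = background level).
#' @export
relative_occupancy <- function(mat, backgrounds) {
  if (!is.null(names(backgrounds))) {
    backgrounds <- backgrounds[colnames(mat)]
  }
  if (any(!is.finite(backgrounds)) || any(backgrounds <= 0)) {
    stop("backgrounds must be positive")
  }
  sweep(mat, 2, backgrounds, "/")
}
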
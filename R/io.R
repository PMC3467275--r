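# Readers and writers for the plain-text formats the pipeline touches.
# All coordinates are 0-based half-open (BED / UCSC refGene native).

#' Read a chromosome sizes table
#'
#' Two-column tab-separated file: chromosome name, length in bp.
#'
#' @param path Path to the file.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) < 2) stop("chrom sizes file must have two columns")
  chrom_info(x[[1]], x[[2]])
}

#' Construct a chromosome info vector
#'
#' @param names Chromosome names.
#' @param lengths Chromosome lengths in bp (must be positive).
#' @return Named numeric vector of lengths.
#' @export
chrom_info <- function(names, lengths) {
  lengths <- as.numeric(lengths)
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("chromosome lengths must be positive")
  }
  if (anyDuplicated(names)) stop("duplicated chromosome names")
  stats::setNames(lengths, as.character(names))
}

#' Write a chromosome sizes table
#' @param info Named vector from [chrom_info()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(info, path) {
  write.table(data.frame(names(info), format(info, scientific = FALSE, trim = TRUE)),
              path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read uniquely mapped reads from a BED6 file
#'
#' Expects at least six tab-separated columns (chrom, start, end, name, score,
#' strand) with 0-based half-open coordinates. Rows violating the mapped-read
#' invariants (start < end, strand in +/-) raise an error naming the offending
#' line; reads on chromosomes absent from `chrom_info` are dropped with a
#' warning giving the dropped count.
#'
#' @param path Path to the BED file.
#' @param chrom_info Optional named vector of chromosome lengths; when given,
#'   reads on unknown chromosomes are removed.
#' @return data.frame with columns chrom, start, end, name, score, strand.
#' @export
read_bed_reads <- function(path, chrom_info = NULL) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  empty <- stats::setNames(
    data.frame(character(), numeric(), numeric(), character(), numeric(),
               character(), stringsAsFactors = FALSE), cols)
  if (file.size(path) == 0) return(empty)
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                  colClasses = "character")
  if (nrow(x) == 0) return(empty)
  if (ncol(x) < 6) stop("BED read file must have >= 6 columns: ", path)
  x <- x[, 1:6]
  names(x) <- cols
  x$start <- suppressWarnings(as.numeric(x$start))
  x$end <- suppressWarnings(as.numeric(x$end))
  x$score <- suppressWarnings(as.numeric(x$score))
  bad <- which(!is.finite(x$start) | !is.finite(x$end))
  if (length(bad)) stop("malformed BED line ", bad[1], " in ", path)
  bad <- which(x$start < 0 | x$start >= x$end)
  if (length(bad)) {
    stop("invalid read interval (need 0 <= start < end) at line ", bad[1],
         " in ", path)
  }
  bad <- which(!x$strand %in% c("+", "-"))
  if (length(bad)) stop("invalid strand at line ", bad[1], " in ", path)
  if (!is.null(chrom_info)) {
    keep <- x$chrom %in% names(chrom_info)
    if (!all(keep)) {
      warning(sum(!keep), " read(s) on chromosomes absent from chrom_info dropped")
      x <- x[keep, , drop = FALSE]
      rownames(x) <- NULL
    }
  }
  x
}

#' Write reads as BED6
#' @param reads data.frame as returned by [read_bed_reads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed_reads <- function(reads, path) {
  out <- data.frame(reads$chrom,
                    format(reads$start, scientific = FALSE, trim = TRUE),
                    format(reads$end, scientific = FALSE, trim = TRUE),
                    reads$name %||% ".", reads$score %||% 0, reads$strand)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a UCSC refGene.txt annotation
#'
#' Parses the UCSC refGene dialect (tab-separated, no header; columns bin,
#' name, chrom, strand, txStart, txEnd, ..., name2). txStart/txEnd are 0-based
#' half-open. Every transcript row becomes one record: splice variants and
#' alternative TSS are kept separate. The TSS is txStart on the plus strand
#' and txEnd on the minus strand (half-open convention); the TES is the
#' opposite end.
#'
#' @param path Path to refGene.txt.
#' @return data.frame with columns transcript_id, gene_symbol, chrom, strand,
#'   tx_start, tx_end, tss, tes.
#' @export
read_refgene <- function(path) {
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) < 6) stop("refGene file must have >= 6 columns")
  genes <- data.frame(
    transcript_id = as.character(x[[2]]),
    gene_symbol = if (ncol(x) >= 13) as.character(x[[13]]) else as.character(x[[2]]),
    chrom = as.character(x[[3]]),
    strand = as.character(x[[4]]),
    tx_start = as.numeric(x[[5]]),
    tx_end = as.numeric(x[[6]]),
    stringsAsFactors = FALSE
  )
  if (any(!genes$strand %in% c("+", "-"))) {
    stop("unknown strand symbol in refGene file: ",
         paste(unique(setdiff(genes$strand, c("+", "-"))), collapse = ", "))
  }
  if (any(genes$tx_start >= genes$tx_end)) stop("txStart must be < txEnd")
  add_tss(genes)
}

# Derive strand-aware TSS/TES columns.
add_tss <- function(genes) {
  genes$tss <- ifelse(genes$strand == "+", genes$tx_start, genes$tx_end)
  genes$tes <- ifelse(genes$strand == "+", genes$tx_end, genes$tx_start)
  genes
}

#' Write genes in UCSC refGene.txt layout
#'
#' Emits the 16-column refGene dialect (unused columns filled with
#' placeholders) so the file round-trips through [read_refgene()].
#'
#' @param genes data.frame with transcript_id, gene_symbol, chrom, strand,
#'   tx_start, tx_end.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_refgene <- function(genes, path) {
  n <- nrow(genes)
  s <- function(v) format(v, scientific = FALSE, trim = TRUE)
  out <- data.frame(
    bin = rep(0L, n), name = genes$transcript_id, chrom = genes$chrom,
    strand = genes$strand, txStart = s(genes$tx_start), txEnd = s(genes$tx_end),
    cdsStart = s(genes$tx_start), cdsEnd = s(genes$tx_end), exonCount = 1L,
    exonStarts = paste0(s(genes$tx_start), ","),
    exonEnds = paste0(s(genes$tx_end), ","),
    score = 0L, name2 = genes$gene_symbol,
    cdsStartStat = "cmpl", cdsEndStat = "cmpl", exonFrames = "0,"
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a binned coverage track as bedGraph
#'
#' One line per non-zero 100-bp bin, `chrom start end value`, preceded by a
#' `track type=bedGraph` header. Zero bins are omitted, so writing and
#' re-reading reproduces non-zero bins exactly.
#'
#' @param track A [bin_midpoints()] / [normalize_track()] track.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "binned_track"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("track type=bedGraph", con)
  bs <- track$bin_size
  for (chrom in names(track$bins)) {
    v <- track$bins[[chrom]]
    nz <- which(v != 0)
    if (!length(nz)) next
    start <- (nz - 1) * bs
    writeLines(paste(chrom, format(start, scientific = FALSE, trim = TRUE),
                     format(start + bs, scientific = FALSE, trim = TRUE),
                     format(v[nz], scientific = FALSE, trim = TRUE,
                            digits = 17), sep = "\t"),
               con)
  }
  invisible(path)
}

#' Read a bedGraph file back into a binned track
#'
#' Inverse of [write_bedgraph()] for tracks with contiguous fixed-width bins.
#'
#' @param path bedGraph path.
#' @param chrom_info Named chromosome lengths.
#' @param bin_size Bin width in bp (default 100).
#' @param total_reads Total mapped reads of the originating sample, if known.
#' @param normalized Whether the stored values were depth-normalized.
#' @return A `binned_track` object.
#' @export
read_bedgraph <- function(path, chrom_info, bin_size = 100, total_reads = NA,
                          normalized = FALSE) {
  lines <- readLines(path)
  lines <- lines[!grepl("^track", lines) & nzchar(lines)]
  bins <- lapply(chrom_info, function(len) numeric(ceiling(len / bin_size)))
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    df <- data.frame(chrom = vapply(parts, `[`, "", 1),
                     start = as.numeric(vapply(parts, `[`, "", 2)),
                     value = as.numeric(vapply(parts, `[`, "", 4)),
                     stringsAsFactors = FALSE)
    for (chrom in unique(df$chrom)) {
      if (!chrom %in% names(bins)) stop("bedGraph chromosome not in chrom_info: ", chrom)
      sel <- df$chrom == chrom
      bins[[chrom]][df$start[sel] / bin_size + 1] <- df$value[sel]
    }
  }
  structure(list(bins = bins, bin_size = bin_size, total_reads = total_reads,
                 normalized = normalized, chrom_info = chrom_info),
            class = "binned_track")
}

#' Write enriched regions as BED5
#'
#' Score column is -log10 of the region's best p-value, capped at 300
#' (p = 0 maps to 300).
#'
#' @param regions data.frame from [call_enriched_regions()] or
#'   [merge_windows()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  score <- ifelse(regions$min_p <= 0, 300, pmin(300, -log10(regions$min_p)))
  out <- data.frame(regions$chrom,
                    format(regions$start, scientific = FALSE, trim = TRUE),
                    format(regions$end, scientific = FALSE, trim = TRUE),
                    paste0("region_", seq_len(nrow(regions))),
                    format(score, scientific = FALSE, trim = TRUE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write an occupancy matrix as TSV
#'
#' Header row is `gene` followed by the column names; rows keep the matrix
#' (annotation) order.
#'
#' @param mat Numeric matrix with gene rownames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an occupancy matrix written by [write_matrix_tsv()]
#' @param path TSV path.
#' @return Numeric matrix with gene rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}
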
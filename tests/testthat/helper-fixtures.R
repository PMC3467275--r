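# Shared fixtures for the suite. Heavy objects (the default synthetic
# dataset) are built once per session and cached.

.cache <- new.env(parent = emptyenv())

# Default synthetic world at the packaged seed, with the derived matrices
# most tests need.
default_dataset <- function() {
  if (is.null(.cache$ds)) {
    genome <- build_genome(sim_config(seed = 1))
    ds <- simulate_dataset(genome)
    occ <- list(
      wt_tss = build_occupancy_matrix(ds$samples$wt, genome$genes),
      wt_body = build_occupancy_matrix(ds$samples$wt, genome$genes,
                                       interval = "body"),
      wt_promoter = build_occupancy_matrix(ds$samples$wt, genome$genes,
                                           interval = "promoter"),
      rd1_tss = build_occupancy_matrix(ds$samples$rd1, genome$genes)
    )
    gfp <- occupancy_matrix(ds$controls, genome$genes, "tss")
    .cache$ds <- list(genome = genome, ds = ds, occ = occ, gfp = gfp,
                      b = gfp_background(gfp), truth = sim_truth(genome))
  }
  .cache$ds
}

# Small hand-buildable sample: midpoints at given positions on one chromosome.
tiny_sample <- function(pos, chrom = "chr1", len = 1e5, total = length(pos)) {
  s <- midpoint_sample(data.frame(chrom = rep(chrom, length(pos)), pos = pos),
                       chrom_info(chrom, len))
  s$total <- total
  s
}

# A minimal gene table.
tiny_genes <- function(tss = 10000, strand = "+", chrom = "chr1",
                       length = 5000) {
  tx_start <- ifelse(strand == "+", tss, tss - length)
  add_tss(data.frame(
    transcript_id = sprintf("t%02d", seq_along(tss)),
    gene_symbol = sprintf("g%02d", seq_along(tss)),
    chrom = chrom, strand = strand, tx_start = tx_start,
    tx_end = tx_start + length, stringsAsFactors = FALSE))
}

# Build an occupancy matrix row-wise from per-mark stage values (units of b).
signature_matrix <- function(k4, k27, b = 10, genes = "g1") {
  mat <- matrix(rep(c(k4, k27) * b, length(genes)), nrow = length(genes),
                byrow = TRUE)
  colnames(mat) <- c(paste0("H3K4me2:", c("E17.5", "PN1", "PN7", "PN15")),
                     paste0("H3K27me3:", c("E17.5", "PN1", "PN7", "PN15")))
  rownames(mat) <- genes
  mat
}

# Adjusted-free Rand index between two partitions (pair-counting oracle).
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}

# Poisson upper tail by direct term-by-term summation (independent oracle).
pois_tail_direct <- function(k, lambda) {
  if (k == 0) return(1)
  i <- 0:(k - 1)
  1 - sum(exp(-lambda + i * log(lambda) - lgamma(i + 1)))
}
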
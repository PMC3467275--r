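test_that("fragment midpoints follow the 190-bp rule and clamp at ends", {
  info <- chrom_info("chr1", 2000)
  reads <- data.frame(chrom = "chr1", start = c(1000, 964, 1990),
                      end = c(1036, 1000, 2000),
                      strand = c("+", "-", "+"), stringsAsFactors = FALSE)
  mids <- fragment_midpoints(reads, info)
  expect_equal(mids$pos, c(1095, 905, 1999))  # +: start+95, -: end-95, clamp
})

test_that("binning counts midpoints into half-open 100-bp bins", {
  info <- chrom_info("chr1", 1000)
  track <- bin_midpoints(tiny_sample(c(50, 150, 199), len = 1000), info)
  expect_equal(track$bins$chr1[1:2], c(1, 2))
  expect_equal(sum(track$bins$chr1), 3)

  boundary <- bin_midpoints(tiny_sample(100, len = 1000), info)
  expect_equal(boundary$bins$chr1[2], 1)  # position 100 belongs to bin 2

  empty <- bin_midpoints(tiny_sample(numeric(0), len = 1000), info)
  expect_true(all(unlist(empty$bins) == 0))
  expect_equal(length(empty$bins$chr1), 10)
})

test_that("midpoint totals are conserved through binning (property)", {
  info <- chrom_info(c("c1", "c2"), c(5e4, 3e4))
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(200, 1)
    mids <- data.frame(chrom = sample(c("c1", "c2"), n, TRUE),
                       pos = sample(3e4, n, TRUE) - 1)
    track <- bin_midpoints(mids, info)
    expect_equal(sum(unlist(track$bins)), n)
  }
})

test_that("binning agrees with a brute-force per-base counter", {
  info <- chrom_info("mini", 10000)
  set.seed(42)
  pos <- sample(0:9999, 500, replace = TRUE)
  track <- bin_midpoints(data.frame(chrom = "mini", pos = pos), info)
  perbase <- tabulate(pos + 1, nbins = 10000)
  brute <- colSums(matrix(perbase, nrow = 100))
  expect_equal(track$bins$mini, brute)
})

test_that("normalization scales to reads per 5 million", {
  info <- chrom_info("chr1", 1000)
  track <- bin_midpoints(tiny_sample(rep(5, 10), len = 1000, total = 2.5e6),
                         info)
  norm <- normalize_track(track)
  expect_equal(norm$bins$chr1[1], 10 * 5e6 / 2.5e6)  # raw 10 -> 20
  expect_true(all(norm$bins$chr1[-1] == 0))
  expect_error(normalize_track(norm), "already normalized")

  at_scale <- bin_midpoints(tiny_sample(c(10, 20), len = 1000, total = 5e6),
                            info)
  expect_equal(normalize_track(at_scale)$bins$chr1,
               bin_midpoints(tiny_sample(c(10, 20), len = 1000), info)$bins$chr1)

  empty <- bin_midpoints(tiny_sample(numeric(0), len = 1000), info)
  expect_error(normalize_track(empty), "total_reads")
})

test_that("normalized tracks are invariant under read duplication", {
  info <- chrom_info("chr1", 5000)
  pos <- c(10, 10, 2300, 4999)
  once <- normalize_track(bin_midpoints(tiny_sample(pos, len = 5000), info))
  twice <- normalize_track(bin_midpoints(tiny_sample(rep(pos, 2), len = 5000),
                                         info))
  expect_equal(once$bins, twice$bins)
})

test_that("TSS metaprofile aggregates strand-aware offsets and sums to 1", {
  g_plus <- tiny_genes(tss = 10000, strand = "+")
  prof <- tss_metaprofile(tiny_sample(10000), g_plus)
  expect_equal(prof$density[prof$position == 0], 1)
  expect_equal(sum(prof$density), 1)

  g_minus <- tiny_genes(tss = 10000, strand = "-")
  prof <- tss_metaprofile(tiny_sample(9000), g_minus)
  expect_equal(prof$density[prof$position == 1000], 1)

  expect_error(tss_metaprofile(tiny_sample(90000), g_plus), "no midpoints")
})

test_that("metaprofile of a strand-symmetric signal is symmetric", {
  genes <- tiny_genes(tss = c(20000, 60000), strand = c("+", "-"))
  set.seed(7)
  offs <- round(c(stats::rnorm(4000, -1000, 300), stats::rnorm(4000, 1000, 300)))
  pos <- c(20000 + offs, 60000 - offs)
  prof <- tss_metaprofile(tiny_sample(pos, len = 1e5), genes)
  half <- nrow(prof) / 2
  left <- rev(prof$density[1:half])
  right <- prof$density[(half + 1):nrow(prof)]
  expect_lt(max(abs(left - right)), 0.02)
})

test_that("LOWESS smoothing is exact on constants and lines", {
  expect_equal(lowess_smooth(rep(3.7, 50), span = 0.3), rep(3.7, 50))
  ramp <- seq(0, 1, length.out = 50)
  expect_equal(lowess_smooth(ramp, span = 0.3), ramp, tolerance = 1e-9)
  expect_error(lowess_smooth(ramp, span = 0), "span")
  expect_error(lowess_smooth(ramp, span = 1.5), "span")
  expect_error(lowess_smooth(1:5, span = 0.5), ">= 10")
})

test_that("LOWESS reduces noise variance on a bimodal profile", {
  set.seed(11)
  x <- seq(-5000, 4900, by = 100)
  truth <- exp(-(x - 1000)^2 / 2e5) + exp(-(x + 1000)^2 / 2e5)
  noisy <- truth + stats::rnorm(length(x), 0, 0.2)
  sm <- lowess_smooth(noisy, span = 0.2)
  expect_lt(stats::var(sm - truth), stats::var(noisy - truth))
})

test_that("prominence-filtered peak finding ignores small wiggles", {
  x <- seq(-5000, 4900, by = 100)
  set.seed(3)
  y <- exp(-(x - 1000)^2 / 2e5) + exp(-(x + 1000)^2 / 2e5) +
    stats::rnorm(length(x), 0, 0.02)
  peaks <- find_profile_peaks(x, lowess_smooth(y, span = 0.1))
  expect_equal(nrow(peaks), 2)
  expect_true(all(abs(abs(peaks$position) - 1000) < 500))
})
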
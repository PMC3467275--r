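test_that("background rate is midpoints per window over the scope", {
  # 1000 midpoints over 10,000 windows of 100 bp -> lambda = 0.1
  info <- chrom_info("chr1", 1e6)
  set.seed(1)
  mids <- data.frame(chrom = "chr1", pos = sample(0:(1e6 - 1), 1000))
  track <- bin_midpoints(mids, info)
  expect_equal(estimate_background_rate(track, "global"), 0.1)

  # two chromosomes with rates 0.1 and 0.3: per-chromosome recovers each,
  # global returns the window-weighted mean
  info2 <- chrom_info(c("cA", "cB"), c(1e5, 1e5))
  set.seed(2)
  mids2 <- rbind(data.frame(chrom = "cA", pos = sample(0:(1e5 - 1), 100)),
                 data.frame(chrom = "cB", pos = sample(0:(1e5 - 1), 300)))
  tr2 <- bin_midpoints(mids2, info2)
  expect_equal(estimate_background_rate(tr2, "per_chromosome"),
               c(cA = 0.1, cB = 0.3))
  expect_equal(estimate_background_rate(tr2, "global"), 0.2)

  empty <- bin_midpoints(data.frame(chrom = character(), pos = numeric()),
                         info)
  expect_error(estimate_background_rate(empty), "empty track")
})

test_that("Poisson upper tail matches direct summation", {
  expect_equal(poisson_upper_tail(0, 5), 1)
  expect_equal(poisson_upper_tail(5, 1), 3.65984682734371e-3,
               tolerance = 1e-10)  # frozen from term-by-term summation
  expect_lt(poisson_upper_tail(20, 0.2), 1e-5)
  expect_error(poisson_upper_tail(3, 0), "lambda")
  expect_error(poisson_upper_tail(-1, 1), "non-negative")
  for (lambda in c(0.1, 1, 10)) {
    for (k in c(1, 7, 50)) {
      expect_lt(abs(poisson_upper_tail(k, lambda) - pois_tail_direct(k, lambda)),
                1e-12)
    }
  }
})

test_that("window scan tests every step and applies a strict threshold", {
  info <- chrom_info("chr1", 1e5)
  zero <- bin_midpoints(data.frame(chrom = character(), pos = numeric()), info)
  expect_equal(nrow(scan_windows(zero)), 0)

  # one loaded bin over a thin background: exactly that window is called
  set.seed(3)
  mids <- data.frame(chrom = "chr1",
                     pos = c(sample(0:(1e5 - 1), 200), rep(50050, 20)))
  track <- bin_midpoints(mids, info)
  hits <- scan_windows(track, caller_config())
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 50000)
  expect_equal(hits$end, 50100)

  # "below threshold" is strict: a window whose p equals the threshold is out
  lambda <- 1
  p5 <- poisson_upper_tail(5, lambda)
  five <- bin_midpoints(data.frame(chrom = "chr1", pos = rep(10, 5)), info)
  cfg_eq <- caller_config(p_threshold = p5)
  expect_equal(nrow(scan_windows(five, cfg_eq, lambda = lambda)), 0)
  cfg_above <- caller_config(p_threshold = p5 * 1.0001)
  expect_equal(nrow(scan_windows(five, cfg_above, lambda = lambda)), 1)
})

test_that("significant windows merge when overlapping or abutting", {
  w <- data.frame(chrom = "chr1", start = c(0, 100, 300),
                  end = c(100, 200, 400), count = c(6, 8, 7),
                  p = c(1e-7, 1e-9, 1e-6), stringsAsFactors = FALSE)
  merged <- merge_windows(w)
  expect_equal(nrow(merged), 2)
  expect_equal(merged$start, c(0, 300))
  expect_equal(merged$end, c(200, 400))
  expect_equal(merged$min_p, c(1e-9, 1e-6))
  expect_equal(merged$max_count, c(8, 7))
  expect_equal(merged$n_windows, c(2L, 1L))

  # overlapping 200-bp windows at 100-bp step collapse to one region
  w2 <- data.frame(chrom = "chr1", start = c(0, 100), end = c(200, 300),
                   count = c(9, 9), p = c(1e-8, 1e-8))
  expect_equal(merge_windows(w2)$end, 300)

  expect_equal(nrow(merge_windows(w[0, ])), 0)
})

test_that("control filtering drops regions enriched in the mock sample", {
  info <- chrom_info("chr1", 1e5)
  regions <- data.frame(chrom = "chr1", start = 50000, end = 50600,
                        min_p = 1e-9, max_count = 12, n_windows = 6)
  set.seed(4)
  bg <- data.frame(chrom = "chr1", pos = sample(0:(1e5 - 1), 200))

  clean <- bin_midpoints(bg, info)
  kept <- filter_by_control(regions, clean, caller_config())
  expect_equal(nrow(kept), 1)
  expect_true(kept$control_p >= 1e-5)

  dirty <- bin_midpoints(rbind(bg, data.frame(chrom = "chr1",
                                              pos = rep(50250, 30))), info)
  expect_equal(nrow(filter_by_control(regions, dirty, caller_config())), 0)

  none <- filter_by_control(regions[0, ], clean, caller_config())
  expect_equal(nrow(none), 0)
})

test_that("caller output is invariant under chromosome order", {
  g <- simulate_peak_genome(chrom_info(c("cA", "cB"), rep(1e5, 2)),
                            n_peaks = 4, peak_width = 1000, fold = 12,
                            lambda_bg = 0.3, seed = 99)
  mk <- function(order) {
    info <- chrom_info(order, rep(1e5, 2))
    tr <- bin_midpoints(midpoint_sample(g$reads, info))
    r <- call_enriched_regions(tr, caller_config(window = 1000, step = 100))
    r[order(r$chrom, r$start), c("chrom", "start", "end", "min_p")]
  }
  a <- mk(c("cA", "cB"))
  b <- mk(c("cB", "cA"))
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("caller config validates its invariants", {
  expect_error(caller_config(window = 100, step = 200), "step")
  expect_error(caller_config(p_threshold = 0), "p_threshold")
  expect_error(caller_config(p_threshold = 1), "p_threshold")
  info <- chrom_info("chr1", 1e4)
  track <- bin_midpoints(tiny_sample(c(5, 250), len = 1e4), info)
  expect_error(scan_windows(track, caller_config(window = 150)), "multiples")
})
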
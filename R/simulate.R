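# Seeded synthetic ChIP-seq generator with planted signature classes.
#
# The generator states a small developmental world: a two-chromosome genome,
# 250 genes in five signature classes, and per-bin Poisson read counts whose
# expected rate is lambda_bg * (1 + fold * shape) over each gene's planted
# domain. Folds per class and stage follow the diagrammatic signatures of the
# modeled system (de novo late activating mark for rod-specific genes, high
# repressive mark for non-rod retinal genes, constant strong activating mark
# for ubiquitous genes, silence for never-expressed genes, decaying activating
# mark for downregulated genes).

SIM_CLASSES <- c("ROD", "NONROD_RETINAL", "UBIQUITOUS", "SILENT", "DOWN")

#' Simulation configuration
#'
#' Defaults state the packaged synthetic world: 2 x 8 Mb chromosomes, 50 genes
#' per signature class, a background of 0.2 reads per 100-bp bin, 190-bp
#' fragments, lognormal per-gene mark-strength multipliers (sdlog 0.3) shared
#' across stages and genotypes, and a rod-loss genotype that scales the whole
#' local H3K4me2 read rate over rod-gene territories by `rd1_rod_scale`.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Chromosome length in bp.
#' @param n_per_class Genes per signature class.
#' @param lambda_bg Background reads per bin.
#' @param bin_size Bin width in bp.
#' @param fragment_len Assumed/simulated fragment size in bp.
#' @param read_len Simulated read length in bp.
#' @param sdlog_h sdlog of the per-gene lognormal mark-strength multiplier.
#' @param rd1_rod_scale Factor applied to the H3K4me2 rate over rod-gene
#'   territories in the rod-less (rd1) genotype.
#' @param flank TSS flank in bp for planted TSS domains.
#' @param bump_center,bump_sd Center offset and width (bp) of the two Gaussian
#'   bumps of the bimodal TSS shape.
#' @param seed Master seed; all per-sample seeds derive from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 2, chrom_length = 8e6, n_per_class = 50,
                       lambda_bg = 0.2, bin_size = 100, fragment_len = 190,
                       read_len = 36, sdlog_h = 0.3, rd1_rod_scale = 0.4,
                       flank = 2500, bump_center = 1000, bump_sd = 300,
                       seed = 1) {
  if (lambda_bg <= 0) stop("lambda_bg must be > 0")
  if (n_per_class < 0) stop("n_per_class must be >= 0")
  structure(list(n_chrom = n_chrom, chrom_length = chrom_length,
                 n_per_class = n_per_class, lambda_bg = lambda_bg,
                 bin_size = bin_size, fragment_len = fragment_len,
                 read_len = read_len, sdlog_h = sdlog_h,
                 rd1_rod_scale = rd1_rod_scale, flank = flank,
                 bump_center = bump_center, bump_sd = bump_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Planted fold tables: fold over background by stage (E17.5, PN1, PN7, PN15)
# and the shape of the planted domain.
#  - flat_gene: flat fold over promoter + TSS window + gene body (the full
#    rod-type domain), making promoter and body per-kb rates exactly equal.
#  - bimodal_tss: two Gaussian bumps at +/- bump_center over the TSS window,
#    normalized so the mean fold over the window equals the stated fold.
#  - flat_tss / flat_tss_body: flat fold over the TSS window (plus body).
signature_folds <- function() {
  list(
    ROD = list(k4 = c(0, 0, 4, 8), k4_shape = "flat_gene",
               k27 = c(0, 0, 0, 0), k27_shape = "flat_tss"),
    NONROD_RETINAL = list(k4 = c(1, 1, 1, 1), k4_shape = "bimodal_tss",
                          k27 = c(6, 6, 6, 6), k27_shape = "flat_tss_body"),
    UBIQUITOUS = list(k4 = c(8, 8, 8, 8), k4_shape = "bimodal_tss",
                      k27 = c(0, 0, 0, 0), k27_shape = "flat_tss"),
    SILENT = list(k4 = c(0, 0, 0, 0), k4_shape = "flat_tss",
                  k27 = c(0, 0, 0, 0), k27_shape = "flat_tss"),
    DOWN = list(k4 = c(8, 6, 2, 0), k4_shape = "bimodal_tss",
                k27 = c(0, 1, 2, 4), k27_shape = "flat_tss")
  )
}

#' Build a synthetic genome with class-annotated genes
#'
#' Places `5 * n_per_class` non-overlapping genes (lengths 2-20 kb, rounded to
#' the bin size, alternating strands, 15-25 kb gaps) on the configured
#' chromosomes, assigns shuffled signature classes, and draws each gene's
#' mark-strength multiplier. Deterministic for a fixed seed.
#'
#' @param cfg A [sim_config()].
#' @return List of class `sim_genome`: chrom_info, genes (gene table with
#'   class and h columns), cfg.
#' @export
build_genome <- function(cfg = sim_config()) {
  info <- chrom_info(paste0("chr", seq_len(cfg$n_chrom)),
                     rep(cfg$chrom_length, cfg$n_chrom))
  n <- cfg$n_per_class * length(SIM_CLASSES)
  genes <- with_seed(cfg$seed, {
    if (n == 0) {
      g <- data.frame(transcript_id = character(), gene_symbol = character(),
                      chrom = character(), strand = character(),
                      tx_start = numeric(), tx_end = numeric(),
                      class = character(), h = numeric(),
                      stringsAsFactors = FALSE)
    } else {
      cls <- sample(rep(SIM_CLASSES, each = cfg$n_per_class))
      h <- stats::rlnorm(n, 0, cfg$sdlog_h)
      len <- round(stats::runif(n, 2000, 20000) / cfg$bin_size) * cfg$bin_size
      gap <- round(stats::runif(n, 15000, 25000) / cfg$bin_size) * cfg$bin_size
      chrom_of <- rep(names(info), length.out = n)
      chrom_of <- chrom_of[order(chrom_of)]
      start <- numeric(n)
      cursor <- stats::setNames(rep(50000, cfg$n_chrom), names(info))
      for (i in seq_len(n)) {
        ch <- chrom_of[i]
        start[i] <- cursor[[ch]]
        cursor[[ch]] <- cursor[[ch]] + len[i] + gap[i]
        if (cursor[[ch]] > info[[ch]] - 50000) {
          stop("genes do not fit in the configured chromosomes")
        }
      }
      g <- data.frame(
        transcript_id = sprintf("tx%04d", seq_len(n)),
        gene_symbol = sprintf("gene%04d", seq_len(n)),
        chrom = chrom_of, strand = rep_len(c("+", "-"), n),
        tx_start = start, tx_end = start + len,
        class = cls, h = h, stringsAsFactors = FALSE)
    }
    g
  })
  structure(list(chrom_info = info, genes = add_tss(genes), cfg = cfg),
            class = "sim_genome")
}

#' Planted-class truth table
#' @param genome A `sim_genome`.
#' @return data.frame with gene, gene_symbol, class, h.
#' @export
sim_truth <- function(genome) {
  data.frame(gene = genome$genes$transcript_id,
             gene_symbol = genome$genes$gene_symbol,
             class = genome$genes$class, h = genome$genes$h,
             stringsAsFactors = FALSE)
}

# Bin index range (1-based) covering [start, end) on a chromosome of nb bins.
bin_range <- function(start, end, bin_size, nb) {
  lo <- max(1L, as.integer(start %/% bin_size) + 1L)
  hi <- min(nb, as.integer(ceiling(end / bin_size)))
  if (hi < lo) integer(0) else lo:hi
}

# Bimodal TSS shape evaluated at offsets (bin centers relative to the TSS),
# normalized to mean 1 over the TSS window so the window-average fold equals
# the stated fold.
bimodal_shape <- function(offsets, cfg) {
  raw <- function(d) {
    exp(-(d - cfg$bump_center)^2 / (2 * cfg$bump_sd^2)) +
      exp(-(d + cfg$bump_center)^2 / (2 * cfg$bump_sd^2))
  }
  grid <- seq(-cfg$flank + cfg$bin_size / 2, cfg$flank - cfg$bin_size / 2,
              by = cfg$bin_size)
  raw(offsets) / mean(raw(grid))
}

# Per-bin expected read rates for one sample, as a list per chromosome.
sim_bin_rates <- function(genome, mark, stage, genotype = "wt") {
  cfg <- genome$cfg
  folds <- signature_folds()
  si <- match(stage, STAGES)
  if (is.na(si)) stop("unknown stage: ", stage)
  bs <- cfg$bin_size
  rates <- lapply(genome$chrom_info, function(len) {
    nb <- as.integer(ceiling(len / bs))
    list(mult = rep(1, nb), scale = rep(1, nb))
  })
  g <- genome$genes
  for (i in seq_len(nrow(g))) {
    spec <- folds[[g$class[i]]]
    if (is.null(spec)) stop("unknown signature class: ", g$class[i])
    f <- if (mark == "H3K4me2") spec$k4[si] else spec$k27[si]
    shape <- if (mark == "H3K4me2") spec$k4_shape else spec$k27_shape
    ch <- g$chrom[i]
    nb <- length(rates[[ch]]$mult)
    # domain of the planted signal, in genome coordinates
    dom <- switch(shape,
      flat_tss = c(g$tss[i] - cfg$flank, g$tss[i] + cfg$flank),
      bimodal_tss = c(g$tss[i] - cfg$flank, g$tss[i] + cfg$flank),
      flat_gene = if (g$strand[i] == "+") {
        c(g$tss[i] - cfg$flank, max(g$tx_end[i], g$tss[i] + cfg$flank))
      } else {
        c(min(g$tx_start[i], g$tss[i] - cfg$flank), g$tss[i] + cfg$flank)
      },
      flat_tss_body = c(min(g$tx_start[i], g$tss[i] - cfg$flank),
                        max(g$tx_end[i], g$tss[i] + cfg$flank))
    )
    if (f > 0) {
      bins <- bin_range(dom[1], dom[2], bs, nb)
      if (length(bins)) {
        s <- if (shape == "bimodal_tss") {
          centers <- (bins - 1) * bs + bs / 2
          off <- if (g$strand[i] == "+") centers - g$tss[i] else g$tss[i] - centers
          bimodal_shape(off, cfg)
        } else 1
        rates[[ch]]$mult[bins] <- rates[[ch]]$mult[bins] + f * g$h[i] * s
      }
    }
    # rod-less genotype: the whole local activating-mark rate over rod-gene
    # territories is scaled down (the rod nuclei are gone)
    if (genotype == "rd1" && g$class[i] == "ROD" && mark == "H3K4me2") {
      terr <- if (g$strand[i] == "+") {
        c(g$tss[i] - cfg$flank, max(g$tx_end[i], g$tss[i] + cfg$flank))
      } else {
        c(min(g$tx_start[i], g$tss[i] - cfg$flank), g$tss[i] + cfg$flank)
      }
      bins <- bin_range(terr[1], terr[2], bs, nb)
      rates[[ch]]$scale[bins] <- cfg$rd1_rod_scale
    }
  }
  lapply(rates, function(r) cfg$lambda_bg * r$mult * r$scale)
}

# Draw Poisson midpoints from per-bin rates; midpoints are kept at least
# fragment_len/2 from chromosome ends so simulated reads stay on-chromosome.
draw_midpoints <- function(rates, cfg, chrom_info) {
  half <- cfg$fragment_len %/% 2
  out <- lapply(names(rates), function(ch) {
    k <- stats::rpois(length(rates[[ch]]), rates[[ch]])
    total <- sum(k)
    if (total == 0) return(NULL)
    bin_start <- rep((which(k > 0) - 1) * cfg$bin_size, k[k > 0])
    pos <- bin_start + floor(stats::runif(total) * cfg$bin_size)
    pos <- pmax(half, pmin(pos, chrom_info[[ch]] - half - cfg$read_len))
    data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(chrom = character(), pos = numeric()) else out
}

# Reads placed so that the fragment-midpoint rule recovers the midpoint:
# plus-strand read starts at pos - fragment_len/2, minus-strand read ends at
# pos + fragment_len/2.
midpoints_to_reads <- function(mids, cfg) {
  n <- nrow(mids)
  half <- cfg$fragment_len %/% 2
  strand <- sample(c("+", "-"), n, replace = TRUE)
  start <- ifelse(strand == "+", mids$pos - half,
                  mids$pos + half - cfg$read_len)
  data.frame(chrom = mids$chrom, start = start, end = start + cfg$read_len,
             name = sprintf("r%07d", seq_len(max(n, 0))[seq_len(n)]),
             score = 0L, strand = strand, stringsAsFactors = FALSE)
}

#' Simulate reads for one mark / stage / genotype
#'
#' Per-bin counts are Poisson with rate `lambda_bg * (1 + fold * shape)` over
#' each gene's planted domain (`* rd1_rod_scale` over rod territories in the
#' rd1 genotype for the activating mark) and `lambda_bg` elsewhere. Reads are
#' placed so the 190-bp fragment-midpoint rule recovers the drawn midpoint
#' exactly; strands are assigned uniformly.
#'
#' @param genome A `sim_genome`.
#' @param mark `"H3K4me2"` or `"H3K27me3"`.
#' @param stage One of `"E17.5", "PN1", "PN7", "PN15"`.
#' @param genotype `"wt"` or `"rd1"`.
#' @param seed RNG seed; derived from the genome's master seed and the sample
#'   key when omitted (fixed master seed implies byte-identical output).
#' @return Reads data.frame (BED6 columns).
#' @export
simulate_mark_reads <- function(genome, mark, stage, genotype = "wt",
                                seed = NULL) {
  cfg <- genome$cfg
  seed <- seed %||% derive_seed(cfg$seed, paste(mark, stage, genotype))
  rates <- sim_bin_rates(genome, mark, stage, genotype)
  with_seed(seed, {
    mids <- draw_midpoints(rates, cfg, genome$chrom_info)
    midpoints_to_reads(mids, cfg)
  })
}

#' Simulate a mock (anti-GFP) control sample
#'
#' Pure background: Poisson(`lambda_bg`) in every bin, no planted signal.
#'
#' @inheritParams simulate_mark_reads
#' @return Reads data.frame (BED6 columns).
#' @export
simulate_control <- function(genome, stage, seed = NULL) {
  cfg <- genome$cfg
  seed <- seed %||% derive_seed(cfg$seed, paste("GFP", stage))
  rates <- lapply(genome$chrom_info, function(len) {
    rep(cfg$lambda_bg, as.integer(ceiling(len / cfg$bin_size)))
  })
  with_seed(seed, {
    mids <- draw_midpoints(rates, cfg, genome$chrom_info)
    midpoints_to_reads(mids, cfg)
  })
}

#' Simulate the full dataset in memory
#'
#' Generates all 2 marks x 4 stages x 2 genotypes samples plus the four
#' stage-matched controls and converts each to a `mark_sample`.
#'
#' @param genome A `sim_genome`.
#' @return List with elements `genome`, `samples` (list `wt` and `rd1`, each a
#'   named list of 8 `mark_sample`s keyed `"mark:stage"`), and `controls`
#'   (named list of 4 `mark_sample`s keyed by stage).
#' @export
simulate_dataset <- function(genome) {
  cfg <- genome$cfg
  mk <- function(reads) midpoint_sample(reads, genome$chrom_info, cfg$fragment_len)
  samples <- lapply(stats::setNames(nm = c("wt", "rd1")), function(gt) {
    out <- list()
    for (mark in MARKS) for (stage in STAGES) {
      out[[sample_key(mark, stage)]] <-
        mk(simulate_mark_reads(genome, mark, stage, gt))
    }
    out
  })
  controls <- lapply(stats::setNames(nm = STAGES), function(stage) {
    mk(simulate_control(genome, stage))
  })
  list(genome = genome, samples = samples, controls = controls)
}

#' Write the fixture set to disk
#'
#' Emits chrom.sizes, refGene.txt, truth.tsv, one BED6 per sample (16 mark
#' samples + 4 controls = 20 files) and a JSON manifest enumerating them.
#' Byte-identical for a fixed seed. On failure the partially written directory
#' is removed.
#'
#' @param genome A `sim_genome`.
#' @param outdir Output directory (created if needed).
#' @return Path to the manifest, invisibly.
#' @export
emit_fixture_set <- function(genome, outdir) {
  created <- !dir.exists(outdir)
  if (created) dir.create(outdir, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok && created) unlink(outdir, recursive = TRUE))
  cfg <- genome$cfg
  write_chrom_sizes(genome$chrom_info, file.path(outdir, "chrom.sizes"))
  write_refgene(genome$genes, file.path(outdir, "refGene.txt"))
  write.table(sim_truth(genome), file.path(outdir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  samples <- list()
  for (gt in c("wt", "rd1")) for (mark in MARKS) for (stage in STAGES) {
    path <- sprintf("%s_%s_%s.bed", mark, stage, gt)
    write_bed_reads(simulate_mark_reads(genome, mark, stage, gt),
                    file.path(outdir, path))
    samples[[length(samples) + 1]] <-
      list(mark = mark, stage = stage, genotype = gt, path = path)
  }
  controls <- list()
  for (stage in STAGES) {
    path <- sprintf("GFP_%s.bed", stage)
    write_bed_reads(simulate_control(genome, stage), file.path(outdir, path))
    controls[[length(controls) + 1]] <- list(stage = stage, path = path)
  }
  manifest <- list(chrom_sizes = "chrom.sizes", genes = "refGene.txt",
                   truth = "truth.tsv", fragment_len = cfg$fragment_len,
                   bin_size = cfg$bin_size, samples = samples,
                   controls = controls)
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  ok <- TRUE
  invisible(manifest_path)
}

#' Load a fixture set from its manifest
#'
#' @param manifest_path Path to a manifest written by [emit_fixture_set()].
#' @return List with `chrom_info`, `genes`, `truth` (or NULL), `fragment_len`,
#'   `samples` (per genotype) and `controls`, mirroring [simulate_dataset()].
#' @export
load_fixture_set <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  base <- dirname(manifest_path)
  info <- read_chrom_sizes(file.path(base, man$chrom_sizes))
  genes <- read_refgene(file.path(base, man$genes))
  truth <- if (!is.null(man$truth) && file.exists(file.path(base, man$truth))) {
    read.delim(file.path(base, man$truth), stringsAsFactors = FALSE)
  }
  fl <- man$fragment_len %||% 190
  mk <- function(path) {
    midpoint_sample(read_bed_reads(file.path(base, path), info), info, fl)
  }
  samples <- list()
  for (i in seq_len(nrow(man$samples))) {
    s <- man$samples[i, ]
    samples[[s$genotype]][[sample_key(s$mark, s$stage)]] <- mk(s$path)
  }
  controls <- list()
  for (i in seq_len(nrow(man$controls))) {
    controls[[man$controls$stage[i]]] <- mk(man$controls$path[i])
  }
  list(chrom_info = info, genes = genes, truth = truth, fragment_len = fl,
       samples = samples, controls = controls)
}

#' Simulate a genome with planted enriched regions
#'
#' Background Poisson(`lambda_bg`) per bin, plus `n_peaks` non-overlapping
#' planted regions of the given width whose rate is
#' `lambda_bg * (1 + fold)` — the fixture for peak-caller calibration and
#' recovery tests.
#'
#' @param chrom_info Named chromosome lengths.
#' @param n_peaks Number of planted regions (0 for a pure-background genome).
#' @param peak_width Region width in bp.
#' @param fold Enrichment fold over background.
#' @param lambda_bg Background reads per bin.
#' @param seed RNG seed.
#' @param bin_size,fragment_len,read_len As in [sim_config()].
#' @return List with `reads` (BED6 data.frame) and `peaks` (chrom, start, end).
#' @export
simulate_peak_genome <- function(chrom_info, n_peaks = 10, peak_width = 1000,
                                 fold = 8, lambda_bg = 0.2, seed = 1,
                                 bin_size = 100, fragment_len = 190,
                                 read_len = 36) {
  cfg <- list(bin_size = bin_size, fragment_len = fragment_len,
              read_len = read_len, lambda_bg = lambda_bg)
  with_seed(seed, {
    rates <- lapply(chrom_info, function(len) {
      rep(lambda_bg, as.integer(ceiling(len / bin_size)))
    })
    peaks <- NULL
    if (n_peaks > 0) {
      # peaks laid out on a coarse lattice with >= 10 kb clearance
      slot_w <- peak_width + 20000
      slots <- do.call(rbind, lapply(names(chrom_info), function(ch) {
        ns <- floor((chrom_info[[ch]] - 20000) / slot_w)
        data.frame(chrom = ch, slot = seq_len(ns), stringsAsFactors = FALSE)
      }))
      if (nrow(slots) < n_peaks) stop("genome too small for requested peaks")
      pick <- slots[sample(nrow(slots), n_peaks), , drop = FALSE]
      start <- 10000 + (pick$slot - 1) * slot_w +
        floor(stats::runif(n_peaks) * 9000 / bin_size) * bin_size
      peaks <- data.frame(chrom = pick$chrom, start = start,
                          end = start + peak_width, stringsAsFactors = FALSE)
      peaks <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
      rownames(peaks) <- NULL
      for (i in seq_len(n_peaks)) {
        bins <- bin_range(peaks$start[i], peaks$end[i], bin_size,
                          length(rates[[peaks$chrom[i]]]))
        rates[[peaks$chrom[i]]][bins] <- lambda_bg * (1 + fold)
      }
    } else {
      peaks <- data.frame(chrom = character(), start = numeric(),
                          end = numeric(), stringsAsFactors = FALSE)
    }
    mids <- draw_midpoints(rates, cfg, chrom_info)
    list(reads = midpoints_to_reads(mids, cfg), peaks = peaks)
  })
}
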
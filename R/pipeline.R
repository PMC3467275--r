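# End-to-end pipeline: simulate or load reads, build tracks, call regions,
# compute occupancies, classify signatures, run comparisons, write artifacts.

#' Pipeline configuration
#'
#' @param outdir Output directory.
#' @param seed Master seed for simulation.
#' @param manifest Optional path to a fixture manifest (see
#'   [emit_fixture_set()]); when `NULL` the dataset is simulated with `sim`.
#' @param sim Named list of [sim_config()] overrides.
#' @param caller Named list of [caller_config()] overrides.
#' @param thresholds Named list of [signature_thresholds()] overrides.
#' @param flank TSS flank in bp for occupancy windows.
#' @param metaprofile_flank,metaprofile_span TSS metaprofile half-window and
#'   LOWESS span.
#' @param use_body Whether the rod screen also requires the gene-body gain.
#' @param kb_constant Occupancy constant (see [interval_occupancy()]).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = tempfile("epimark_run_"), seed = 1,
                            manifest = NULL, sim = list(), caller = list(),
                            thresholds = list(), flank = 2500,
                            metaprofile_flank = 5000, metaprofile_span = 0.05,
                            use_body = FALSE, kb_constant = 1) {
  structure(list(outdir = outdir, seed = seed, manifest = manifest, sim = sim,
                 caller = do.call(caller_config, caller),
                 thresholds = do.call(signature_thresholds, thresholds),
                 flank = flank, metaprofile_flank = metaprofile_flank,
                 metaprofile_span = metaprofile_span, use_body = use_body,
                 kb_constant = kb_constant),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#' @param path JSON file with [pipeline_config()] fields.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Run the full analysis pipeline
#'
#' Stages: (1) load the fixture manifest or simulate the dataset; (2) build
#' and write depth-normalized bedGraph tracks; (3) call enriched regions per
#' wild-type sample with stage-matched control filtering; (4) compute TSS,
#' promoter and gene-body occupancy matrices for both genotypes and the
#' control background `b`; (5) classify signatures; (6) build the H3K4me2
#' TSS metaprofile at the final stage; (7) run promoter-vs-body comparisons
#' and the wild-type-vs-rd1 contrast on the rod-labelled and non-rod gene
#' sets. All artifacts are written as plain text under `outdir`, along with a
#' run log recording parameters (and input checksums when reading a fixture).
#' Re-running with the same configuration reproduces identical outputs.
#'
#' @param config A [pipeline_config()], or a path to a JSON config.
#' @return Invisibly, a list with the in-memory results (dataset, matrices,
#'   background, labels, regions, comparisons, output paths).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log <- list(seed = config$seed, caller = unclass(config$caller),
              thresholds = unclass(config$thresholds), flank = config$flank)

  # -- input stage -----------------------------------------------------------
  if (!is.null(config$manifest)) {
    if (!file.exists(config$manifest)) {
      stop("fixture manifest not found: ", config$manifest)
    }
    fx <- load_fixture_set(config$manifest)
    genes <- fx$genes
    chrominfo <- fx$chrom_info
    truth <- fx$truth
    samples <- fx$samples
    controls <- fx$controls
    files <- list.files(dirname(config$manifest), full.names = TRUE)
    log$input_md5 <- as.list(tools::md5sum(files))
  } else {
    cfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
    genome <- build_genome(cfg)
    ds <- simulate_dataset(genome)
    genes <- genome$genes
    chrominfo <- genome$chrom_info
    truth <- sim_truth(genome)
    samples <- ds$samples
    controls <- ds$controls
    log$sim <- unclass(cfg)
  }
  out <- function(...) file.path(config$outdir, ...)

  # -- tracks and enrichment calling (wild type) -----------------------------
  regions <- list()
  for (key in names(samples$wt)) {
    track <- bin_midpoints(samples$wt[[key]])
    write_bedgraph(normalize_track(track),
                   out(paste0(gsub(":", "_", key), "_wt.bedgraph")))
    stage <- strsplit(key, ":", fixed = TRUE)[[1]][2]
    ctrack <- bin_midpoints(controls[[stage]])
    regions[[key]] <- call_enriched_regions(track, config$caller, ctrack)
    write_regions_bed(regions[[key]],
                      out(paste0("regions_", gsub(":", "_", key), "_wt.bed")))
  }

  # -- occupancy matrices ----------------------------------------------------
  occ <- list()
  for (gt in names(samples)) {
    for (iv in c("tss", "promoter", "body")) {
      occ[[gt]][[iv]] <- build_occupancy_matrix(
        samples[[gt]], genes, interval = iv, flank = config$flank,
        kb_constant = config$kb_constant)
      write_matrix_tsv(occ[[gt]][[iv]],
                       out(sprintf("occupancy_%s_%s.tsv", iv, gt)))
    }
  }
  gfp_occ <- occupancy_matrix(controls, genes, "tss", config$flank,
                              kb_constant = config$kb_constant)
  write_matrix_tsv(gfp_occ, out("occupancy_tss_gfp.tsv"))
  b <- gfp_background(gfp_occ)
  log$gfp_background <- b

  # -- signature classification ---------------------------------------------
  labels <- classify_signatures(occ$wt$tss, b, body_mat = occ$wt$body,
                                thresholds = config$thresholds,
                                use_body = config$use_body)
  write.table(labels, out("labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  # -- TSS metaprofile (activating mark, final stage) ------------------------
  profile <- tss_metaprofile(samples$wt[[sample_key("H3K4me2", "PN15")]],
                             genes, flank = config$metaprofile_flank)
  profile <- lowess_smooth(profile, config$metaprofile_span)
  write.table(profile, out("metaprofile_H3K4me2_PN15.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # -- comparisons -----------------------------------------------------------
  pb <- compare_promoter_body(occ$wt$promoter, occ$wt$body)
  write.table(pb, out("promoter_body.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  bg_wt <- vapply(samples$wt, sample_background_occupancy, 0, genes = genes)
  bg_rd1 <- vapply(samples$rd1, sample_background_occupancy, 0, genes = genes)
  rel_wt <- relative_occupancy(occ$wt$tss, bg_wt)
  rel_rd1 <- relative_occupancy(occ$rd1$tss, bg_rd1)
  rod_set <- labels$gene[labels$label == "ROD_SPECIFIC"]
  nonrod_set <- labels$gene[!labels$label %in% c("ROD_SPECIFIC", "NO_MARK")]
  genotype <- list()
  if (length(rod_set) >= 2) {
    genotype$rod <- compare_genotypes(rel_wt, rel_rd1, rod_set)
  }
  if (length(nonrod_set) >= 2) {
    genotype$nonrod <- compare_genotypes(rel_wt, rel_rd1, nonrod_set)
  }
  gt_df <- do.call(rbind, lapply(names(genotype), function(nm) {
    g <- genotype[[nm]]
    data.frame(set = nm, n_genes = g$n_genes, fold = g$fold, t = g$test$t,
               df = g$test$df, p = g$test$p, stars = g$test$stars,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(gt_df)) {
    write.table(gt_df, out("genotype_comparison.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  jsonlite::write_json(log, out("run_log.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(genes = genes, chrom_info = chrominfo, truth = truth,
                 samples = samples, controls = controls, regions = regions,
                 occupancy = occ, gfp_occupancy = gfp_occ, background = b,
                 labels = labels, metaprofile = profile,
                 promoter_body = pb, genotype = genotype,
                 outdir = config$outdir))
}
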
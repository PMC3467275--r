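# Equal-variance two-sample comparisons: promoter vs gene body, wt vs mutant.

#' Significance stars
#'
#' `***` for P < 0.001, `**` for 0.001 <= P < 0.01, `*` for 0.01 <= P < 0.05,
#' `ns` otherwise.
#'
#' @param p P-value(s).
#' @return Character vector of annotations.
#' @export
p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Two-sample t-test assuming equal variances
#'
#' Classic pooled-variance t statistic with `n_x + n_y - 2` degrees of freedom
#' and a two-sided p-value.
#'
#' @param x,y Numeric samples (each of length >= 2).
#' @return List of class `pooled_t`: mean_x, mean_y, t, df, p, stars.
#' @export
pooled_t_test <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  if (nx < 2 || ny < 2) stop("need >= 2 values per group")
  df <- nx + ny - 2
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / df
  if (sp2 <= 0) stop("zero pooled variance: t statistic undefined")
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  p <- 2 * stats::pt(-abs(t), df)
  structure(list(mean_x = mean(x), mean_y = mean(y), t = t, df = df, p = p,
                 stars = p_stars(p)),
            class = "pooled_t")
}

#' @export
print.pooled_t <- function(x, ...) {
  cat(sprintf("pooled t-test: t = %.4f, df = %d, p = %.4g (%s)\n",
              x$t, x$df, x$p, x$stars))
  cat(sprintf("  means: %.4g vs %.4g\n", x$mean_x, x$mean_y))
  invisible(x)
}

#' Compare promoter and gene-body occupancy per mark and stage
#'
#' For each mark/stage column, runs an equal-variance two-sample t-test
#' between the per-gene promoter occupancies and the per-gene gene-body
#' occupancies (both already length-normalized per kb).
#'
#' @param promoter_mat,body_mat Occupancy matrices over the same genes and
#'   columns.
#' @param genes Optional character vector restricting the gene set.
#' @return data.frame with one row per column: mark, stage, mean_promoter,
#'   mean_body, t, df, p, stars.
#' @export
compare_promoter_body <- function(promoter_mat, body_mat, genes = NULL) {
  stopifnot(identical(colnames(promoter_mat), colnames(body_mat)))
  if (!is.null(genes)) {
    if (length(genes) < 2) stop("gene set must contain >= 2 genes")
    promoter_mat <- promoter_mat[genes, , drop = FALSE]
    body_mat <- body_mat[genes, , drop = FALSE]
  }
  if (nrow(promoter_mat) < 2) stop("gene set must contain >= 2 genes")
  rows <- lapply(colnames(promoter_mat), function(cn) {
    tt <- pooled_t_test(promoter_mat[, cn], body_mat[, cn])
    ms <- strsplit(cn, ":", fixed = TRUE)[[1]]
    data.frame(mark = ms[1], stage = ms[2], mean_promoter = tt$mean_x,
               mean_body = tt$mean_y, t = tt$t, df = tt$df, p = tt$p,
               stars = tt$stars, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare occupancy between genotypes on a gene set
#'
#' Averages each gene's occupancy over the selected mark/stage columns in both
#' genotypes, reports the mean fold change (wild type over mutant) and an
#' equal-variance two-sample t-test. Occupancy matrices should normally be
#' background-relative (see [relative_occupancy()]): raw occupancies carry a
#' library-composition factor (libraries with more enriched signal spend a
#' larger share of their reads inside peaks), which biases between-genotype
#' comparisons even at genes whose marking is unchanged.
#'
#' @param wt_mat,mut_mat Occupancy matrices for the two genotypes (same
#'   columns).
#' @param genes Character vector of genes to compare (default: all rows).
#' @param mark Mark whose columns are compared.
#' @param stages Stages to average over.
#' @return List of class `genotype_comparison`: fold (mean wt / mean mutant,
#'   `Inf` with `infinite_fold = TRUE` when the mutant mean is 0), the group
#'   means, and `test`, a [pooled_t_test()] result.
#' @export
compare_genotypes <- function(wt_mat, mut_mat, genes = NULL, mark = "H3K4me2",
                              stages = STAGES) {
  stopifnot(identical(colnames(wt_mat), colnames(mut_mat)))
  genes <- genes %||% rownames(wt_mat)
  cols <- sample_key(mark, stages)
  x <- rowMeans(wt_mat[genes, cols, drop = FALSE])
  y <- rowMeans(mut_mat[genes, cols, drop = FALSE])
  test <- pooled_t_test(x, y)
  infinite <- mean(y) == 0
  fold <- if (infinite) Inf else mean(x) / mean(y)
  structure(list(fold = fold, infinite_fold = infinite, mean_wt = mean(x),
                 mean_mut = mean(y), n_genes = length(genes), mark = mark,
                 stages = stages, test = test),
            class = "genotype_comparison")
}

#' @export
print.genotype_comparison <- function(x, ...) {
  cat(sprintf("%s occupancy, %d genes: wt/mutant fold = %.3g (p = %.3g, %s)\n",
              x$mark, x$n_genes, x$fold, x$test$p, x$test$stars))
  invisible(x)
}
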
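# Average-linkage hierarchical clustering of occupancy profiles.

#' Uncentered-correlation distance
#'
#' `d(x, y) = 1 - sum(x * y) / (||x|| * ||y||)` — the default similarity of
#' the classic Gene Cluster software. Rows with zero norm are assigned
#' distance 1 to every other row.
#'
#' @param x Numeric matrix (rows are profiles).
#' @return A `dist` object.
#' @export
uncentered_cor_dist <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  zero <- nrm == 0
  xs <- x / ifelse(nrm == 0, 1, nrm)
  sim <- tcrossprod(xs)
  sim[zero, ] <- 0
  sim[, zero] <- 0
  d <- 1 - sim
  stats::as.dist(d)
}

#' Average-linkage hierarchical clustering
#'
#' Agglomerative clustering with average linkage (UPGMA) on Euclidean or
#' uncentered-correlation distances, optionally cut into flat clusters.
#'
#' @param x Numeric matrix (rows are genes / profiles) or a precomputed
#'   `dist`.
#' @param metric `"euclidean"` or `"uncentered"` (ignored for a `dist` input).
#' @param k Number of flat clusters to cut, or `NULL`.
#' @param h Cut height, or `NULL`.
#' @return List of class `epimark_clust` with elements `hclust` (the merge
#'   tree) and `clusters` (named integer vector, or `NULL` when no cut was
#'   requested).
#' @export
hierarchical_cluster <- function(x, metric = c("euclidean", "uncentered"),
                                 k = NULL, h = NULL) {
  if (inherits(x, "dist")) {
    d <- x
  } else {
    if (nrow(x) < 2) stop("need >= 2 rows to cluster")
    metric <- match.arg(metric)
    d <- if (metric == "euclidean") stats::dist(x) else uncentered_cor_dist(x)
  }
  tree <- stats::hclust(d, method = "average")
  clusters <- if (!is.null(k) || !is.null(h)) stats::cutree(tree, k = k, h = h)
  structure(list(hclust = tree, clusters = clusters), class = "epimark_clust")
}

#' @export
print.epimark_clust <- function(x, ...) {
  cat("<epimark_clust> average linkage,", length(x$hclust$height) + 1,
      "leaves")
  if (!is.null(x$clusters)) cat(",", length(unique(x$clusters)), "flat clusters")
  cat("\n")
  invisible(x)
}
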
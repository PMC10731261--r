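#' Pairwise Euclidean distances between ISN edge vectors
#'
#' Plain (unsquared) l2 distances between the rows of the edge-weight matrix.
#'
#' @param W n x k matrix of per-sample ISN edge weights.
#' @return symmetric n x n matrix with zero diagonal.
#' @export
isn_distance_matrix <- function(W) {
  W <- as.matrix(W)
  # ||w_i - w_j||^2 = ||w_i||^2 + ||w_j||^2 - 2 w_i'w_j, via BLAS; k is
  # typically in the tens of thousands, where a pairwise loop is impractical
  G <- tcrossprod(W)
  s <- diag(G)
  D <- sqrt(pmax(outer(s, s, `+`) - 2 * G, 0))
  diag(D) <- 0
  dimnames(D) <- list(rownames(W), rownames(W))
  (D + t(D)) / 2
}

#' Ward's minimum-variance linkage on unsquared Euclidean distances
#'
#' Agglomeration under the ward.D2 convention: the Lance-Williams update runs
#' on squared dissimilarities and heights are reported in distance units.
#'
#' @param D distance matrix (or \code{dist}).
#' @return an \code{hclust} object.
#' @export
ward_linkage <- function(D) {
  if (!inherits(D, "dist")) {
    D <- as.matrix(D)
    if (nrow(D) < 2L) stop("need at least 2 observations")
    D <- stats::as.dist(D)
  }
  stats::hclust(D, method = "ward.D2")
}

#' Cluster individuals from their ISN edge vectors
#'
#' Composition of the clustering stage: Euclidean distances between ISN edge
#' vectors, ward.D2 linkage, and automatic cluster-count detection by the
#' dynamic hybrid tree cut.
#'
#' @param W n x k matrix of ISN edge weights (rows = individuals), or an
#'   \code{"isn_collection"}.
#' @param deep_split tree-cut aggressiveness, 0-4 (default 1).
#' @param min_cluster_size minimum cluster size for the tree cut (default 20).
#' @param ... further arguments passed to [dynamic_tree_cut()].
#' @return list of class \code{"clustering_result"}: \code{labels} (1..C),
#'   \code{n_clusters}, \code{linkage} (the \code{hclust} tree),
#'   \code{distance_metric}.
#' @export
cluster_individuals <- function(W, deep_split = 1L, min_cluster_size = 20L, ...) {
  if (inherits(W, "isn_collection")) W <- vectorize_isns(W)
  W <- as.matrix(W)
  stopifnot(nrow(W) >= 3L)
  D <- isn_distance_matrix(W)
  tree <- ward_linkage(D)
  labels <- dynamic_tree_cut(tree, D, deep_split = deep_split,
                             min_cluster_size = min_cluster_size, ...)
  if (!is.null(rownames(W))) names(labels) <- rownames(W)
  structure(list(labels = labels,
                 n_clusters = length(unique(labels[labels > 0L])),
                 linkage = tree, distance_metric = "euclidean"),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("clustering_result: %d clusters over %d individuals\n",
              x$n_clusters, length(x$labels)))
  print(table(x$labels))
  invisible(x)
}
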
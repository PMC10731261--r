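#' Mean ISN over a subset of individuals
#'
#' Entrywise average of the members' ISN matrices, returned in symmetric
#' matrix form (zero diagonal).
#'
#' @param collection an \code{"isn_collection"}.
#' @param member_ids sample ids or integer indices of the subset.
#' @return symmetric r x r matrix.
#' @export
mean_isn <- function(collection, member_ids = collection$sample_ids) {
  stopifnot(inherits(collection, "isn_collection"))
  if (is.character(member_ids))
    member_ids <- match(member_ids, collection$sample_ids)
  if (length(member_ids) == 0L || anyNA(member_ids))
    stop("empty or unknown member subset")
  w <- colMeans(collection$W[member_ids, , drop = FALSE])
  fold_edge_vector(w, collection$node_ids)
}

#' Binarize a weighted network by keeping the top fraction of edges
#'
#' Retains the \code{ceiling(fraction * k)} largest-weight edges of the
#' upper triangle (k = r(r-1)/2) as 1, the rest as 0. Ties at the cutoff are
#' broken by edge-index order (row-major upper triangle), so the retained
#' count is exact for any input.
#'
#' @param network symmetric r x r weight matrix (diagonal ignored).
#' @param fraction fraction of edges to keep, in (0, 1] (default 0.01).
#' @return list of class \code{"binary_network"}: \code{adjacency} (0/1,
#'   hollow symmetric), \code{node_ids}, \code{threshold_used} (smallest
#'   retained weight), \code{retained_fraction}, \code{n_retained}.
#' @export
binarize_top_edges <- function(network, fraction = 0.01) {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  network <- as.matrix(network)
  r <- nrow(network)
  ei <- edge_index(r)
  w <- network[ei]
  k <- length(w)
  n_keep <- ceiling(fraction * k)
  keep <- order(-w, seq_len(k))[seq_len(n_keep)]
  A <- matrix(0L, r, r)
  A[ei[keep, , drop = FALSE]] <- 1L
  A[ei[keep, c(2, 1), drop = FALSE]] <- 1L
  ids <- rownames(network)
  if (is.null(ids)) ids <- paste0("V", seq_len(r))
  dimnames(A) <- list(ids, ids)
  structure(list(adjacency = A, node_ids = ids,
                 threshold_used = min(w[keep]),
                 retained_fraction = n_keep / k, n_retained = n_keep),
            class = "binary_network")
}

#' Largest connected component of a binary network
#'
#' Isolated nodes count as size-1 components; ties in component size are
#' broken by the smallest node index.
#'
#' @param network a \code{"binary_network"} or 0/1 adjacency matrix.
#' @return list with \code{nodes} (indices), \code{node_ids}, and
#'   \code{edges} (m x 2 index matrix, i < j).
#' @export
largest_connected_component <- function(network) {
  A <- if (inherits(network, "binary_network")) network$adjacency else as.matrix(network)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  comp <- igraph::components(g)
  best_size <- max(comp$csize)
  cands <- which(comp$csize == best_size)
  first_node <- vapply(cands, function(cc) min(which(comp$membership == cc)), 1)
  pick <- cands[which.min(first_node)]
  nodes <- which(comp$membership == pick)
  ei <- edge_index(nrow(A))
  on_edge <- A[ei] != 0 & ei[, 1] %in% nodes & ei[, 2] %in% nodes
  ids <- rownames(A)
  list(nodes = unname(nodes),
       node_ids = if (is.null(ids)) NULL else ids[nodes],
       edges = ei[on_edge, , drop = FALSE])
}

#' Graph filtration curve: mean LCC degree against an edge threshold
#'
#' For each threshold t, the subgraph keeps edges with weight strictly larger
#' than t; the curve value is the mean node degree of the largest connected
#' component of that subgraph, computed over the LCC's own nodes. A subgraph
#' with no edges has value 0.
#'
#' @param network symmetric r x r weight matrix (diagonal ignored).
#' @param thresholds ascending numeric vector of edge thresholds.
#' @return list of class \code{"filtration_curve"} with \code{thresholds} and
#'   \code{values}.
#' @export
filtration_curve <- function(network, thresholds) {
  stopifnot(!is.unsorted(thresholds))
  network <- as.matrix(network)
  r <- nrow(network)
  ei <- edge_index(r)
  w <- network[ei]
  values <- vapply(thresholds, function(t) {
    keep <- which(w > t)
    if (length(keep) == 0L) return(0)
    sub <- ei[keep, , drop = FALSE]
    g <- igraph::graph_from_edgelist(sub, directed = FALSE)
    comp <- igraph::components(g)
    # nodes absent from the edge list are isolated: size-1 components
    pick <- which.max(comp$csize)
    if (comp$csize[pick] < 2L) return(0)
    nodes <- which(comp$membership == pick)
    n_edges <- sum(sub[, 1] %in% nodes)  # both endpoints in the same component
    2 * n_edges / length(nodes)
  }, numeric(1))
  structure(list(thresholds = thresholds, values = values),
            class = "filtration_curve")
}

#' Shared threshold grid for comparable filtration curves
#'
#' Evenly spaced quantiles (default 50, at probabilities 0.02..1.00) of the
#' pooled positive edge weights of all ISNs; sharing the grid across samples
#' makes pointwise means and standard deviations meaningful.
#'
#' @param collection an \code{"isn_collection"}.
#' @param n_thresholds number of grid points (default 50).
#' @return ascending numeric vector.
#' @export
default_threshold_grid <- function(collection, n_thresholds = 50L) {
  w <- as.vector(collection$W)
  w <- w[w > 0]
  if (length(w) == 0L) stop("all ISN edge weights are zero")
  sort(unname(stats::quantile(w, probs = seq_len(n_thresholds) / n_thresholds)))
}

#' Per-cluster mean and sd of the ISN filtration curves
#'
#' @param collection an \code{"isn_collection"}.
#' @param labels complete cluster labels (length n, values 1..C).
#' @param thresholds shared ascending threshold grid; default
#'   [default_threshold_grid()].
#' @return data.frame with columns \code{cluster}, \code{threshold},
#'   \code{mean}, \code{sd}.
#' @export
curves_by_cluster <- function(collection, labels,
                              thresholds = default_threshold_grid(collection)) {
  stopifnot(inherits(collection, "isn_collection"),
            length(labels) == nrow(collection$W))
  curves <- t(vapply(seq_len(nrow(collection$W)), function(s) {
    filtration_curve(fold_edge_vector(collection$W[s, ]), thresholds)$values
  }, numeric(length(thresholds))))
  out <- do.call(rbind, lapply(sort(unique(labels)), function(cl) {
    rows <- curves[labels == cl, , drop = FALSE]
    data.frame(cluster = cl, threshold = thresholds,
               mean = colMeans(rows),
               sd = if (nrow(rows) > 1L) apply(rows, 2L, stats::sd) else 0)
  }))
  rownames(out) <- NULL
  out
}
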
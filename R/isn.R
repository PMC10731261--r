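#' Global co-expression + phenotype network over the selected features
#'
#' Edge score between features i and j is the sum of three Pearson
#' correlations: \code{cor(V_i, V_j) + cor(V_i, Z) + cor(V_j, Z)}, hence in
#' [-3, 3]. The diagonal is not part of the network and is set to \code{NA}.
#'
#' @param V n x r matrix of selected features (both views, columns = nodes).
#' @param Z length-n phenotype.
#' @param include_phenotype include the two feature-phenotype correlations in
#'   the edge score (default TRUE, the published supervised score). With
#'   FALSE the edge score is the plain feature-feature correlation, the
#'   "uninformed" flavor; see the methods vignette for when this matters.
#' @return list of class \code{"global_network"}: \code{edge_weights} (r x r
#'   symmetric, \code{NA} diagonal), \code{node_ids}, \code{n_samples_used}.
#' @export
global_network <- function(V, Z, include_phenotype = TRUE) {
  V <- as.matrix(V)
  stopifnot(ncol(V) >= 2L, nrow(V) == length(Z))
  check_nonconstant(V, Z)
  R <- stats::cor(V)
  E <- if (include_phenotype) {
    rz <- drop(stats::cor(V, Z))
    R + outer(rz, rz, `+`)
  } else R
  diag(E) <- NA_real_
  ids <- colnames(V)
  if (is.null(ids)) ids <- paste0("V", seq_len(ncol(V)))
  dimnames(E) <- list(ids, ids)
  structure(list(edge_weights = E, node_ids = ids, n_samples_used = nrow(V)),
            class = "global_network")
}

check_nonconstant <- function(V, Z, context = "") {
  v <- matrixStats_colVars(V)
  if (any(v < 1e-14)) {
    bad <- which(v < 1e-14)[1]
    nm <- colnames(V)[bad]
    stop("constant feature column ", if (is.null(nm)) bad else nm, context,
         ": Pearson correlation undefined")
  }
  if (stats::var(Z) < 1e-14)
    stop("constant phenotype", context, ": Pearson correlation undefined")
}

# colVars without extra dependencies
matrixStats_colVars <- function(M) {
  n <- nrow(M)
  (colSums(M^2) - colSums(M)^2 / n) / (n - 1)
}

# Ordered upper-triangle edge list (i < j), row-major: (1,2),(1,3),...,(2,3),...
edge_index <- function(r) {
  i <- rep.int(seq_len(r - 1L), times = (r - 1L):1L)
  j <- sequence((r - 1L):1L, from = 2L:r)
  cbind(i = i, j = j)
}

#' Leave-one-out individual-specific networks
#'
#' For each sample s the ISN edge weight is the absolute difference between
#' the global edge score (all n samples) and the same score recomputed with
#' sample s left out. \code{method = "incremental"} (default) updates the
#' sufficient statistics (sums, squares, cross-products) in O(1) per edge and
#' sample; \code{method = "naive"} recomputes every leave-one-out correlation
#' from scratch and is kept as an independent cross-check.
#'
#' @param V n x r matrix of selected features.
#' @param Z length-n phenotype.
#' @param method \code{"incremental"} or \code{"naive"}.
#' @param include_phenotype include the feature-phenotype correlation terms
#'   in the edge score (default TRUE; see [global_network()]).
#' @param chunk_size number of edges processed per block in the incremental
#'   path (memory/speed trade-off).
#' @return list of class \code{"isn_collection"}: \code{W} (n x k,
#'   non-negative; k = r(r-1)/2), \code{edge_index} (k x 2, row-major upper
#'   triangle), \code{sample_ids}, \code{node_ids}, \code{global} (the
#'   [global_network()]).
#' @export
individual_specific_networks <- function(V, Z,
                                         method = c("incremental", "naive"),
                                         include_phenotype = TRUE,
                                         chunk_size = 4096L) {
  method <- match.arg(method)
  V <- as.matrix(V)
  n <- nrow(V); r <- ncol(V)
  stopifnot(n >= 3L, r >= 2L, length(Z) == n)
  g <- global_network(V, Z, include_phenotype = include_phenotype)
  ei <- edge_index(r)
  e_glob <- g$edge_weights[ei]
  W <- if (method == "naive") isn_naive(V, Z, ei, e_glob, include_phenotype)
       else isn_incremental(V, Z, ei, e_glob, chunk_size, include_phenotype)
  sample_ids <- rownames(V)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  dimnames(W) <- list(sample_ids,
                      paste(g$node_ids[ei[, 1]], g$node_ids[ei[, 2]], sep = "|"))
  structure(list(W = W, edge_index = ei, sample_ids = sample_ids,
                 node_ids = g$node_ids, global = g),
            class = "isn_collection")
}

isn_naive <- function(V, Z, ei, e_glob, include_phenotype = TRUE) {
  n <- nrow(V)
  W <- matrix(NA_real_, n, nrow(ei))
  for (s in seq_len(n)) {
    Vs <- V[-s, , drop = FALSE]
    vr <- matrixStats_colVars(Vs)
    if (any(vr < 1e-14))
      stop("leaving out sample ", s, " makes feature ",
           which(vr < 1e-14)[1], " constant")
    if (stats::var(Z[-s]) < 1e-14)
      stop("leaving out sample ", s, " makes the phenotype constant")
    R <- stats::cor(Vs)
    e_loo <- R[ei]
    if (include_phenotype) {
      rz <- drop(stats::cor(Vs, Z[-s]))
      e_loo <- e_loo + rz[ei[, 1]] + rz[ei[, 2]]
    }
    W[s, ] <- abs(e_glob - e_loo)
  }
  W
}

isn_incremental <- function(V, Z, ei, e_glob, chunk_size,
                            include_phenotype = TRUE) {
  n <- nrow(V); r <- ncol(V); k <- nrow(ei)
  m <- n - 1L  # leave-one-out sample count
  Sx <- colSums(V)
  Sxx <- colSums(V^2)
  C <- crossprod(V)              # pairwise sum of products
  SZ <- sum(Z); SZZ <- sum(Z^2)
  CZ <- drop(crossprod(V, Z))

  # per-sample leave-one-out feature sums and variance terms (n x r)
  L1 <- sweep(-V, 2L, Sx, `+`)                   # Sx - x_s
  D  <- m * sweep(-V^2, 2L, Sxx, `+`) - L1^2     # m*Sxx' - Sx'^2
  # D / (m*(m-1)) is the leave-one-out variance; < 1e-14 treated as constant
  if (any(D / (m * (m - 1)) < 1e-14))
    stop("a leave-one-out subsample has a constant feature column")
  LZ <- SZ - Z                                   # per-sample scalar
  DZ <- m * (SZZ - Z^2) - LZ^2
  if (any(DZ / (m * (m - 1)) < 1e-14))
    stop("a leave-one-out subsample has a constant phenotype")

  # leave-one-out feature-phenotype correlations (n x r)
  RZ <- if (include_phenotype) {
    numZ <- m * sweep(-V * Z, 2L, CZ, `+`) - L1 * LZ
    numZ / sqrt(D * DZ)
  } else matrix(0, n, r)

  W <- matrix(NA_real_, n, k)
  for (start in seq(1L, k, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, k)
    i <- ei[idx, 1L]; j <- ei[idx, 2L]
    num <- m * (rep(C[ei[idx, , drop = FALSE]], each = n) - V[, i] * V[, j]) -
      L1[, i] * L1[, j]
    dim(num) <- c(n, length(idx))
    rloo <- num / sqrt(D[, i] * D[, j])
    e_loo <- rloo + RZ[, i] + RZ[, j]
    W[, idx] <- abs(rep(e_glob[idx], each = n) - e_loo)
  }
  W
}

#' Edge-vector representation of the ISNs
#'
#' Returns the n x k matrix whose rows are the per-sample ISN edge weights in
#' the fixed row-major upper-triangle order; this is the coordinate
#' representation used for clustering.
#'
#' @param collection an \code{"isn_collection"}.
#' @return numeric matrix n x k.
#' @export
vectorize_isns <- function(collection) {
  stopifnot(inherits(collection, "isn_collection"))
  collection$W
}

#' Fold one sample's edge vector back into a symmetric r x r matrix
#'
#' Inverse of the vectorization; the diagonal is 0.
#'
#' @param w length-k edge vector (row-major upper triangle).
#' @param node_ids optional node names (length r).
#' @return symmetric r x r matrix.
#' @export
fold_edge_vector <- function(w, node_ids = NULL) {
  k <- length(w)
  r <- as.integer((1 + sqrt(1 + 8 * k)) / 2)
  stopifnot(r * (r - 1L) / 2L == k)
  M <- matrix(0, r, r)
  ei <- edge_index(r)
  M[ei] <- w
  M[ei[, c(2, 1)]] <- w
  if (!is.null(node_ids)) dimnames(M) <- list(node_ids, node_ids)
  M
}
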
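#' Column-standardize a matrix
#'
#' Centers every column to mean 0 and scales to standard deviation 1
#' (denominator n - 1). The canonical-correlation objective is written in
#' inner products that equal scaled correlations only for standardized data,
#' so both views and the phenotype are standardized before fitting.
#'
#' @param M numeric matrix (samples x features) or numeric vector.
#' @return matrix (or vector) of the same shape.
#' @export
standardize <- function(M) {
  if (is.null(dim(M))) return(drop(standardize(matrix(M, ncol = 1L))))
  M <- as.matrix(M)
  s <- apply(M, 2L, stats::sd)
  bad <- which(s < 1e-12)
  if (length(bad)) {
    nm <- colnames(M)[bad]
    if (is.null(nm)) nm <- as.character(bad)
    stop("zero-variance column(s): ", paste(nm, collapse = ", "))
  }
  scale(M, center = TRUE, scale = s)[, , drop = FALSE]
}

#' Configuration for supervised sparse multiple CCA
#'
#' @param c1,c2 l1 bounds on the canonical weights of views X and Y; must lie
#'   in \code{[1, sqrt(p)]} / \code{[1, sqrt(q)]} (an l1 bound below 1 is
#'   infeasible together with unit l2 norm). \code{NULL} defers the choice to
#'   the caller (e.g. cross-validation).
#' @param w1,w2,w3 non-negative weights of the three correlation terms
#'   (view-view, X-phenotype, Y-phenotype); all 1 by default, the netMUG
#'   setting.
#' @param n_subsamples number of feature-subsampling runs (default 100).
#' @param subsample_prop_x,subsample_prop_y proportion of features drawn per
#'   run from each view (defaults 0.8).
#' @param max_iter,tol alternating-update iteration cap and convergence
#'   tolerance on the weight change (defaults 200, 1e-6).
#' @param seed integer seed for the subsampling draws; \code{NULL} = current
#'   RNG state.
#' @return object of class \code{"smcca_config"}.
#' @export
smcca_config <- function(c1 = NULL, c2 = NULL, w1 = 1, w2 = 1, w3 = 1,
                         n_subsamples = 100L,
                         subsample_prop_x = 0.8, subsample_prop_y = 0.8,
                         max_iter = 200L, tol = 1e-6, seed = NULL) {
  stopifnot(w1 >= 0, w2 >= 0, w3 >= 0, n_subsamples >= 1L,
            subsample_prop_x > 0, subsample_prop_x <= 1,
            subsample_prop_y > 0, subsample_prop_y <= 1,
            max_iter >= 1L, tol > 0)
  if (!is.null(c1) && c1 < 1) stop("c1 must be >= 1")
  if (!is.null(c2) && c2 < 1) stop("c2 must be >= 1")
  structure(list(c1 = c1, c2 = c2, w1 = w1, w2 = w2, w3 = w3,
                 n_subsamples = as.integer(n_subsamples),
                 subsample_prop_x = subsample_prop_x,
                 subsample_prop_y = subsample_prop_y,
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "smcca_config")
}

soft_threshold <- function(x, delta) sign(x) * pmax(abs(x) - delta, 0)

l2norm <- function(x) sqrt(sum(x^2))

# Solve max u'g s.t. ||u||_2 <= 1, ||u||_1 <= c: soft-threshold g at the
# smallest delta >= 0 whose l2-normalized result satisfies the l1 bound;
# delta = 0 if the bound is already met. The normalized l1 norm
# f(delta) = ||S(g,delta)||_1 / ||S(g,delta)||_2 is piecewise smooth and
# decreasing between the sorted magnitudes of g, so the crossing segment is
# located from prefix sums and delta is then bisected on the closed-form
# segment expression (scalar ops only, essentially to machine precision).
penalized_unit_vector <- function(g, c) {
  if (all(g == 0)) stop("all-zero gradient: degenerate input")
  u <- g / l2norm(g)
  if (sum(abs(u)) <= c) return(u)
  a <- sort(abs(g), decreasing = TRUE)
  p <- length(a)
  S1 <- cumsum(a)
  S2 <- cumsum(a^2)
  mseq <- seq_len(p - 1L)
  dk <- a[mseq + 1L]  # knots: the (m+1)-th largest magnitude
  l2k2 <- pmax(S2[mseq] - 2 * dk * S1[mseq] + mseq * dk^2, 0)
  fk <- ifelse(l2k2 > 0, (S1[mseq] - mseq * dk) / sqrt(l2k2), 1)
  m <- which(fk >= c)[1L]  # f increases as delta sweeps down the knots
  if (is.na(m)) {
    m <- p; lo <- 0; hi <- a[p]
  } else {
    lo <- a[m + 1L]; hi <- a[m]
  }
  S1m <- S1[m]; S2m <- S2[m]
  fseg <- function(d) (S1m - m * d) / sqrt(S2m - 2 * d * S1m + m * d^2)
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    if (fseg(mid) > c) lo <- mid else hi <- mid
    if (hi - lo <= 1e-15 * a[1L]) break
  }
  su <- soft_threshold(g, hi)
  su / l2norm(su)
}

smcca_objective <- function(a, b, XtY, XtZ, YtZ, w1, w2, w3) {
  w1 * drop(crossprod(a, XtY %*% b)) + w2 * sum(a * XtZ) + w3 * sum(b * YtZ)
}

#' Fit supervised sparse multiple CCA by alternating penalized updates
#'
#' Maximizes \code{w1 a'X'Yb + w2 a'X'Z + w3 b'Y'Z} subject to unit l2 norms
#' and l1 bounds \code{||a||_1 <= c1}, \code{||b||_1 <= c2}. Each half-step
#' solves its subproblem exactly (soft-thresholding with a bisection on the
#' threshold), so the objective is non-decreasing across iterations. Weights
#' are initialized from the leading singular vectors of \code{X'Y}, with the
#' sign combination that maximizes the objective.
#'
#' @param X,Y standardized views (n x p, n x q).
#' @param Z standardized phenotype (length n). Ignored when \code{w2 = w3 = 0}.
#' @param cfg an [smcca_config()] with \code{c1}, \code{c2} set.
#' @return list of class \code{"canonical_weights"}: \code{a}, \code{b},
#'   \code{objective_value}, \code{iterations}, \code{converged}.
#' @export
smcca_fit <- function(X, Y, Z = NULL, cfg = smcca_config()) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  p <- ncol(X); q <- ncol(Y)
  stopifnot(nrow(X) == nrow(Y))
  c1 <- if (is.null(cfg$c1)) sqrt(p) else cfg$c1
  c2 <- if (is.null(cfg$c2)) sqrt(q) else cfg$c2
  if (c1 < 1 || c1 > sqrt(p) + 1e-8) stop("c1 must lie in [1, sqrt(p)]")
  if (c2 < 1 || c2 > sqrt(q) + 1e-8) stop("c2 must lie in [1, sqrt(q)]")
  if (is.null(Z)) Z <- numeric(nrow(X))
  stopifnot(length(Z) == nrow(X))

  XtY <- crossprod(X, Y)
  XtZ <- drop(crossprod(X, Z))
  YtZ <- drop(crossprod(Y, Z))

  run_from <- function(b0) {
    a <- NULL; b <- b0
    converged <- FALSE
    obj <- obj_prev <- -Inf
    iter <- 0L
    for (iter in seq_len(cfg$max_iter)) {
      a_new <- penalized_unit_vector(cfg$w1 * drop(XtY %*% b) + cfg$w2 * XtZ, c1)
      gb <- cfg$w1 * drop(crossprod(XtY, a_new)) + cfg$w3 * YtZ
      b_new <- penalized_unit_vector(gb, c2)
      delta <- if (is.null(a)) Inf
               else max(max(abs(a_new - a)), max(abs(b_new - b)))
      a <- a_new; b <- b_new
      obj <- sum(b * gb) + cfg$w2 * sum(a * XtZ)
      if (delta < cfg$tol) { converged <- TRUE; break }
      # plateau guard: near-tied optima can make the weights oscillate
      # without measurable objective gain; treat that as converged
      if (obj - obj_prev < 1e-10 * (1 + abs(obj))) { converged <- TRUE; break }
      obj_prev <- obj
    }
    list(a = a, b = b, obj = obj, iter = iter, converged = converged)
  }

  # the alternating scheme is a local method; start from the leading right
  # singular vector (both signs), the supervised direction Y'Z when present,
  # and, at small dimension, every coordinate axis (sparse corners)
  sv <- svd(XtY, nu = 1L, nv = 1L)
  starts <- list(sv$v[, 1L], -sv$v[, 1L])
  if (cfg$w3 > 0 && any(YtZ != 0)) starts <- c(starts, list(YtZ / l2norm(YtZ)))
  if (q <= 12L) starts <- c(starts, lapply(seq_len(q), function(j) {
    e <- numeric(q); e[j] <- 1; e
  }))
  fits <- lapply(starts, function(b0)
    run_from(penalized_unit_vector(b0, c2)))
  fit <- fits[[which.max(vapply(fits, `[[`, numeric(1), "obj"))]]
  a <- fit$a; b <- fit$b
  iter <- fit$iter
  converged <- fit$converged
  if (!converged)
    warning("smcca_fit did not converge in ", cfg$max_iter, " iterations")
  structure(list(a = stats::setNames(a, colnames(X)),
                 b = stats::setNames(b, colnames(Y)),
                 objective_value = smcca_objective(a, b, XtY, XtZ, YtZ,
                                                   cfg$w1, cfg$w2, cfg$w3),
                 c1 = c1, c2 = c2, iterations = iter, converged = converged),
            class = "canonical_weights")
}

#' Choose the sparsity bounds by k-fold cross-validation
#'
#' For every pair on the grid, fits the supervised sparse CCA on the training
#' folds and scores the held-out canonical correlation
#' \code{cor(X_test a, Y_test b)}; returns the pair with the best mean
#' held-out correlation. Standardization is refit within each training fold.
#'
#' @param X,Y,Z raw (unstandardized) views and phenotype.
#' @param grid_c1,grid_c2 candidate values for the two l1 bounds.
#' @param n_folds number of folds (default 5).
#' @param cfg an [smcca_config()]; its \code{c1}, \code{c2} are ignored.
#' @param seed seed for the fold assignment.
#' @return list with \code{c1}, \code{c2}, and \code{grid} (a data.frame of
#'   mean held-out correlation per pair).
#' @export
cross_validate_sparsity <- function(X, Y, Z, grid_c1, grid_c2, n_folds = 5L,
                                    cfg = smcca_config(), seed = NULL) {
  stopifnot(length(grid_c1) >= 1L, length(grid_c2) >= 1L,
            nrow(X) >= n_folds)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(X)
  fold <- sample(rep_len(seq_len(n_folds), n))
  if (min(table(fold)) < 3L) stop("a fold has fewer than 3 samples")
  grid <- expand.grid(c1 = grid_c1, c2 = grid_c2, KEEP.OUT.ATTRS = FALSE)
  grid$mean_cor <- NA_real_
  for (g in seq_len(nrow(grid))) {
    cfg_g <- cfg
    cfg_g$c1 <- grid$c1[g]; cfg_g$c2 <- grid$c2[g]
    cors <- numeric(n_folds)
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      fit <- smcca_fit(standardize(X[tr, , drop = FALSE]),
                       standardize(Y[tr, , drop = FALSE]),
                       standardize(Z[tr]), cfg_g)
      u <- as.matrix(X[!tr, , drop = FALSE]) %*% fit$a
      v <- as.matrix(Y[!tr, , drop = FALSE]) %*% fit$b
      cors[f] <- if (stats::sd(u) < 1e-12 || stats::sd(v) < 1e-12) 0
                 else stats::cor(u, v)
    }
    grid$mean_cor[g] <- mean(cors)
  }
  best <- which.max(grid$mean_cor)
  list(c1 = grid$c1[best], c2 = grid$c2[best], grid = grid)
}

#' Robust feature-similarity matrix via feature subsampling
#'
#' Runs the supervised sparse CCA \code{n_subsamples} times, each on a random
#' feature subset of each view, embeds the absolute outer product of the
#' concatenated canonical weights into the full (p+q) x (p+q) space
#' (unsampled entries contribute 0 for that run), averages over runs, and
#' rescales by the maximum so that \code{max(S) = 1}.
#'
#' @param X,Y,Z raw views and phenotype (standardized internally, per
#'   subsample).
#' @param cfg an [smcca_config()].
#' @return list of class \code{"similarity_matrix"}: \code{S} ((p+q) x (p+q),
#'   entries in [0,1]), \code{feature_ids}, \code{view_of}.
#' @export
subsampled_similarity <- function(X, Y, Z, cfg = smcca_config()) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  p <- ncol(X); q <- ncol(Y)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  kx <- ceiling(cfg$subsample_prop_x * p)
  ky <- ceiling(cfg$subsample_prop_y * q)
  Zs <- standardize(Z)
  S <- matrix(0, p + q, p + q)
  n_ok <- 0L
  for (run in seq_len(cfg$n_subsamples)) {
    ix <- sort(sample.int(p, kx))
    iy <- sort(sample.int(q, ky))
    fit <- tryCatch(
      smcca_fit(standardize(X[, ix, drop = FALSE]),
                standardize(Y[, iy, drop = FALSE]), Zs, scale_c(cfg, kx, ky)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ab <- c(fit$a, fit$b)
    idx <- c(ix, p + iy)
    S[idx, idx] <- S[idx, idx] + similarity_from_weights(ab)
    n_ok <- n_ok + 1L
  }
  if (n_ok == 0L) stop("all subsampling runs failed")
  S <- S / cfg$n_subsamples
  m <- max(S)
  if (m == 0) stop("similarity matrix is identically zero (no signal)")
  S <- S / m
  ids <- c(colnames(X), colnames(Y))
  if (is.null(ids) || length(ids) != p + q)
    ids <- c(paste0("X", seq_len(p)), paste0("Y", seq_len(q)))
  dimnames(S) <- list(ids, ids)
  structure(list(S = S, feature_ids = ids,
                 view_of = rep(c("X", "Y"), c(p, q))),
            class = "similarity_matrix")
}

# When cfg$c1/c2 are NULL the l1 bound defaults to no sparsity at the
# subsample's own dimension; explicit bounds are clipped to stay feasible
# for the smaller subsampled feature space.
scale_c <- function(cfg, kx, ky) {
  if (!is.null(cfg$c1)) cfg$c1 <- max(1, min(cfg$c1, sqrt(kx)))
  if (!is.null(cfg$c2)) cfg$c2 <- max(1, min(cfg$c2, sqrt(ky)))
  cfg
}

#' Similarity layer of a single run: absolute outer product of the
#' concatenated canonical weights.
#'
#' @param ab concatenated weight vector \code{c(a, b)}.
#' @return symmetric non-negative matrix \code{|ab ab'|}.
#' @export
similarity_from_weights <- function(ab) abs(tcrossprod(ab))

#' Detect cross-view feature modules from the similarity matrix
#'
#' Complete-linkage hierarchical clustering of the features on the distance
#' \code{1 - S}, cut statically at \code{cut_height} (default 0.999, i.e.
#' very close to 1); clusters that are singletons or contain features from a
#' single view only are discarded.
#'
#' @param sim a \code{"similarity_matrix"} from [subsampled_similarity()].
#' @param cut_height dendrogram cut height in (0, 1].
#' @return list of modules, each a list with \code{member_indices} (into the
#'   concatenated X-then-Y feature space), \code{x_members}, \code{y_members}.
#' @export
detect_modules <- function(sim, cut_height = 0.999) {
  stopifnot(inherits(sim, "similarity_matrix"),
            cut_height > 0, cut_height <= 1)
  S <- sim$S
  if (any(S < 0) || any(S > 1)) stop("similarity entries must lie in [0, 1]")
  if (nrow(S) < 2L) return(list())
  tree <- stats::hclust(stats::as.dist(1 - S), method = "complete")
  groups <- stats::cutree(tree, h = cut_height)
  out <- list()
  for (gid in unique(groups)) {
    members <- which(groups == gid)
    if (length(members) < 2L) next
    vx <- members[sim$view_of[members] == "X"]
    vy <- members[sim$view_of[members] == "Y"]
    if (length(vx) == 0L || length(vy) == 0L) next
    out[[length(out) + 1L]] <- list(member_indices = unname(members),
                                    x_members = unname(vx),
                                    y_members = unname(vy))
  }
  out
}

#' Per-view indices of the features retained in the detected modules
#'
#' @param modules output of [detect_modules()].
#' @param p number of features in view X (to split the concatenated index
#'   space back into views).
#' @return list with sorted, deduplicated \code{x_indices} and
#'   \code{y_indices}.
#' @export
select_features <- function(modules, p) {
  all_idx <- as.integer(sort(unique(unlist(lapply(modules, `[[`,
                                                  "member_indices")))))
  list(x_indices = all_idx[all_idx <= p],
       y_indices = all_idx[all_idx > p] - as.integer(p))
}
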
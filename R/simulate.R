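#' Simulation configuration for the synthetic two-view benchmark
#'
#' Describes the generative design used throughout the package's validation:
#' two views of \code{n_features_per_view} columns each, of which
#' \code{n_noise} are pure standard-normal noise, \code{n_corr} are latent
#' pairs correlated across the views, and \code{n_clust} are cross-view
#' correlated latents additionally scaled per sample by a cluster-specific
#' multiplier. Cluster membership also shifts the mean of the extraneous
#' phenotype \code{Z}. Finally the signal (corr + clust) columns of each view
#' are mixed by a random square matrix with uniform entries, so that single
#' observed columns carry blended signal, as in real omics/image data.
#'
#' @param n_samples number of individuals (default 1000).
#' @param n_features_per_view columns per view (default 1000).
#' @param n_noise number of standard-normal noise columns (default 600).
#' @param n_corr number of cross-view correlated latent pairs (default 200).
#' @param n_clust number of cluster-bearing latent pairs (default 200).
#' @param n_clusters number of balanced sample clusters (default 3).
#' @param corr_cov_range range of cross-view covariances for the corr block
#'   (default \code{c(0.5, 0.8)}); endpoints must lie in (0, 1).
#' @param clust_cov_range range for the clust block (default \code{c(0.8, 1)}).
#' @param cluster_multipliers per-cluster row multipliers applied to the clust
#'   latents (default \code{c(1, 2, 3)}).
#' @param phenotype_means per-cluster phenotype means (default \code{c(-1, 0, 1)}).
#' @param phenotype_sd phenotype standard deviation within cluster (default 1).
#' @param mixing_range range of the uniform entries of the per-view square
#'   mixing matrix applied to the signal columns (default \code{c(-3, 3)});
#'   \code{NULL} disables mixing (identity), useful for didactic checks.
#' @param seed integer seed; \code{NULL} uses the current RNG state.
#' @return an object of class \code{"sim_config"} (a validated list).
#' @seealso [simulate_multiview()]
#' @export
sim_config <- function(n_samples = 1000L, n_features_per_view = 1000L,
                       n_noise = 600L, n_corr = 200L, n_clust = 200L,
                       n_clusters = 3L,
                       corr_cov_range = c(0.5, 0.8),
                       clust_cov_range = c(0.8, 1),
                       cluster_multipliers = c(1, 2, 3),
                       phenotype_means = c(-1, 0, 1),
                       phenotype_sd = 1,
                       mixing_range = c(-3, 3),
                       seed = NULL) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_features_per_view = as.integer(n_features_per_view),
              n_noise = as.integer(n_noise), n_corr = as.integer(n_corr),
              n_clust = as.integer(n_clust), n_clusters = as.integer(n_clusters),
              corr_cov_range = as.numeric(corr_cov_range),
              clust_cov_range = as.numeric(clust_cov_range),
              cluster_multipliers = as.numeric(cluster_multipliers),
              phenotype_means = as.numeric(phenotype_means),
              phenotype_sd = as.numeric(phenotype_sd),
              mixing_range = if (is.null(mixing_range)) NULL else as.numeric(mixing_range),
              seed = if (is.null(seed)) NULL else as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_samples >= 1L, cfg$n_features_per_view >= 1L,
            cfg$n_noise >= 0L, cfg$n_corr >= 0L, cfg$n_clust >= 0L,
            cfg$n_clusters >= 1L, cfg$phenotype_sd > 0)
  if (cfg$n_noise + cfg$n_corr + cfg$n_clust != cfg$n_features_per_view)
    stop("n_noise + n_corr + n_clust must equal n_features_per_view")
  if (length(cfg$cluster_multipliers) != cfg$n_clusters ||
      length(cfg$phenotype_means) != cfg$n_clusters)
    stop("cluster_multipliers and phenotype_means must have length n_clusters")
  for (nm in c("corr_cov_range", "clust_cov_range")) {
    r <- cfg[[nm]]
    if (length(r) != 2L || r[1] > r[2]) stop(nm, " must be an ordered pair")
    if (any(r <= 0)) stop(nm, " endpoints must be positive")
  }
  # |rho| < 1 keeps the block covariance [[I,R],[R,I]] positive definite;
  # the clust block may touch 1 (a U(lo,1) draw is < 1 almost surely).
  if (cfg$corr_cov_range[2] >= 1)
    stop("corr_cov_range endpoints must be < 1")
  if (cfg$clust_cov_range[2] > 1)
    stop("clust_cov_range endpoints must be <= 1")
  if (!is.null(cfg$mixing_range) &&
      (length(cfg$mixing_range) != 2L || cfg$mixing_range[1] > cfg$mixing_range[2]))
    stop("mixing_range must be an ordered pair or NULL")
  invisible(cfg)
}

# Near-balanced group sizes: floor/ceil counts differing by <= 1.
balanced_sizes <- function(n, k) {
  base <- n %/% k
  sizes <- rep(base, k)
  extra <- n - base * k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

# One latent pair per column: x ~ N(0,1), y = rho*x + sqrt(1-rho^2)*noise,
# exactly the bivariate margin of the block-MVN with Sigma = [[I,R],[R,I]].
draw_latent_block <- function(n, m, cov_range) {
  rho <- stats::runif(m, cov_range[1], cov_range[2])
  x <- matrix(stats::rnorm(n * m), n, m)
  y <- sweep(x, 2, rho, `*`) +
    sweep(matrix(stats::rnorm(n * m), n, m), 2, sqrt(1 - rho^2), `*`)
  list(x = x, y = y, rho = rho)
}

#' Simulate a two-view dataset with cross-linked features and planted clusters
#'
#' Draws noise, cross-view correlated and cluster-bearing latent columns for
#' each view, scales the cluster-bearing latents per sample by the multiplier
#' of its (randomly permuted, near-balanced) cluster, samples the phenotype
#' from a cluster-shifted normal, and mixes the signal columns of each view by
#' an independent uniform square matrix. Emitted columns are ordered signal
#' first (corr then clust positions) then noise; feature ids record the
#' ground-truth role of each column (\code{corr_k}, \code{clust_k},
#' \code{noise_k}) so feature-selection recall can be measured.
#'
#' @param config a [sim_config()].
#' @return a list of class \code{"multiview_data"} with elements \code{X},
#'   \code{Y} (n x p numeric matrices), \code{Z} (length-n phenotype),
#'   \code{labels} (true cluster ids 1..n_clusters), \code{sample_ids},
#'   \code{feature_ids} (list with \code{x}, \code{y}), and \code{config}.
#' @examples
#' d <- simulate_multiview(sim_config(n_samples = 60, n_features_per_view = 30,
#'                                    n_noise = 18, n_corr = 6, n_clust = 6,
#'                                    seed = 1))
#' dim(d$X); table(d$labels)
#' @export
simulate_multiview <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_samples
  p <- config$n_features_per_view

  sizes <- balanced_sizes(n, config$n_clusters)
  labels <- sample(rep.int(seq_len(config$n_clusters), sizes))

  corr <- draw_latent_block(n, config$n_corr, config$corr_cov_range)
  clust <- draw_latent_block(n, config$n_clust, config$clust_cov_range)
  mult <- config$cluster_multipliers[labels]
  if (config$n_clust > 0) {
    clust$x <- clust$x * mult
    clust$y <- clust$y * mult
  }

  Z <- stats::rnorm(n, mean = config$phenotype_means[labels],
                    sd = config$phenotype_sd)

  Xsig <- cbind(corr$x, clust$x)
  Ysig <- cbind(corr$y, clust$y)
  n_sig <- ncol(Xsig)
  if (!is.null(config$mixing_range) && n_sig > 0) {
    Mx <- matrix(stats::runif(n_sig^2, config$mixing_range[1],
                              config$mixing_range[2]), n_sig, n_sig)
    My <- matrix(stats::runif(n_sig^2, config$mixing_range[1],
                              config$mixing_range[2]), n_sig, n_sig)
    Xsig <- Xsig %*% Mx
    Ysig <- Ysig %*% My
  }

  noise_x <- matrix(stats::rnorm(n * config$n_noise), n, config$n_noise)
  noise_y <- matrix(stats::rnorm(n * config$n_noise), n, config$n_noise)

  roles <- c(if (config$n_corr > 0) paste0("corr_", seq_len(config$n_corr)),
             if (config$n_clust > 0) paste0("clust_", seq_len(config$n_clust)),
             if (config$n_noise > 0) paste0("noise_", seq_len(config$n_noise)))
  sample_ids <- sprintf("S%04d", seq_len(n))
  X <- cbind(Xsig, noise_x)
  Y <- cbind(Ysig, noise_y)
  dimnames(X) <- list(sample_ids, paste0("X_", roles))
  dimnames(Y) <- list(sample_ids, paste0("Y_", roles))

  structure(list(X = X, Y = Y, Z = stats::setNames(Z, sample_ids),
                 labels = stats::setNames(labels, sample_ids),
                 sample_ids = sample_ids,
                 feature_ids = list(x = colnames(X), y = colnames(Y)),
                 config = config),
            class = "multiview_data")
}

#' @export
print.multiview_data <- function(x, ...) {
  cat(sprintf("multiview_data: n = %d, p = %d, q = %d\n",
              nrow(x$X), ncol(x$X), ncol(x$Y)))
  if (!is.null(x$labels))
    cat("true clusters:", paste(table(x$labels), collapse = "/"), "\n")
  invisible(x)
}

#' Ground-truth role of each simulated feature
#'
#' @param feature_ids character vector of simulated feature ids.
#' @return factor with levels \code{corr}, \code{clust}, \code{noise}.
#' @export
feature_roles <- function(feature_ids) {
  factor(sub("^[XY]_([a-z]+)_[0-9]+$", "\\1", feature_ids),
         levels = c("corr", "clust", "noise"))
}
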
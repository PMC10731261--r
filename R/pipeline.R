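derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) + 999983 * k) %% 2147483647)
}

#' Run the full netMUG workflow on two views and a phenotype
#'
#' Executes the three stages in order: (1) phenotype-supervised sparse
#' multiple CCA with feature subsampling, module detection on the averaged
#' similarity matrix and feature selection; (2) leave-one-out
#' individual-specific networks over the selected features; (3) ward.D2
#' clustering of the ISN edge vectors with the dynamic hybrid tree cut.
#'
#' @param X,Y raw sample x feature views (aligned on rows).
#' @param Z extraneous phenotype (length n).
#' @param truth optional ground-truth labels for evaluation.
#' @param smcca_cfg an [smcca_config()]. If its \code{c1}/\code{c2} are
#'   \code{NULL} they are chosen by 5-fold cross-validation over
#'   \code{cv_grid}.
#' @param cv_grid candidate l1 bounds expressed as fractions of
#'   \code{sqrt(p)} (and \code{sqrt(q)}); default \code{c(0.3, 0.5, 0.8)}.
#' @param cut_height module-detection dendrogram cut (default 0.999).
#' @param deep_split,min_cluster_size tree-cut parameters (defaults 1, 20).
#' @param isn_include_phenotype include the feature-phenotype correlation
#'   terms in the ISN edge score (default TRUE, the published supervised
#'   score; see [global_network()] and the methods vignette).
#' @param seed master seed; stage seeds are derived from it deterministically.
#' @return list of class \code{"netmug_result"} with \code{sparsity},
#'   \code{similarity}, \code{modules}, \code{selected} (per-view indices),
#'   \code{isns}, \code{clustering}, \code{report}.
#' @examples
#' \donttest{
#' d <- simulate_multiview(sim_config(n_samples = 90, n_features_per_view = 60,
#'                                    n_noise = 36, n_corr = 12, n_clust = 12,
#'                                    seed = 7))
#' res <- run_netmug(d$X, d$Y, d$Z, truth = d$labels,
#'                   smcca_cfg = smcca_config(n_subsamples = 10, seed = 7),
#'                   min_cluster_size = 10, seed = 7)
#' res$report
#' }
#' @export
run_netmug <- function(X, Y, Z, truth = NULL,
                       smcca_cfg = smcca_config(),
                       cv_grid = c(0.3, 0.5, 0.8),
                       cut_height = 0.999, deep_split = 1L,
                       min_cluster_size = 20L, isn_include_phenotype = TRUE,
                       seed = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (nrow(Y) != n || length(Z) != n)
    stop("X, Y and Z must agree on the number of samples")
  p <- ncol(X); q <- ncol(Y)

  cv <- NULL
  if (is.null(smcca_cfg$c1) || is.null(smcca_cfg$c2)) {
    grid_c1 <- pmax(1, pmin(cv_grid * sqrt(p), sqrt(p)))
    grid_c2 <- pmax(1, pmin(cv_grid * sqrt(q), sqrt(q)))
    cv <- cross_validate_sparsity(X, Y, Z, grid_c1, grid_c2,
                                  cfg = smcca_cfg, seed = derive_seed(seed, 1L))
    smcca_cfg$c1 <- cv$c1
    smcca_cfg$c2 <- cv$c2
  }
  smcca_cfg$seed <- derive_seed(seed, 2L)

  sim <- subsampled_similarity(X, Y, Z, smcca_cfg)
  modules <- detect_modules(sim, cut_height = cut_height)
  if (length(modules) == 0L)
    stop("feature selection retained no cross-view module")
  sel <- select_features(modules, p)
  V <- cbind(X[, sel$x_indices, drop = FALSE], Y[, sel$y_indices, drop = FALSE])
  if (ncol(V) < 2L) stop("fewer than 2 features selected")

  isns <- individual_specific_networks(V, Z,
                                       include_phenotype = isn_include_phenotype)
  clustering <- cluster_individuals(isns, deep_split = deep_split,
                                    min_cluster_size = min_cluster_size)
  report <- evaluate_clustering(clustering$labels, truth = truth, z = Z)

  structure(list(sparsity = list(c1 = smcca_cfg$c1, c2 = smcca_cfg$c2, cv = cv),
                 similarity = sim, modules = modules, selected = sel,
                 isns = isns, clustering = clustering, report = report),
            class = "netmug_result")
}

#' @export
print.netmug_result <- function(x, ...) {
  cat(sprintf("netmug_result: %d modules, %d selected features (%d + %d)\n",
              length(x$modules),
              length(x$selected$x_indices) + length(x$selected$y_indices),
              length(x$selected$x_indices), length(x$selected$y_indices)))
  print(x$report)
  invisible(x)
}

#' Run the pipeline from a single configuration (and persist artifacts)
#'
#' The configuration is a list (or path to a JSON file) holding exactly one
#' of: a \code{simulation} block (arguments to [sim_config()]) or an
#' \code{inputs} block with paths \code{x}, \code{y}, \code{z} and optional
#' \code{truth} (TSV files in the package dialect). Optional blocks:
#' \code{smcca} (arguments to [smcca_config()]), and scalars
#' \code{cut_height}, \code{deep_split}, \code{min_cluster_size},
#' \code{top_fraction}, \code{seed}.
#'
#' @param config list or path to a JSON config file.
#' @param out_dir output directory; created if missing. \code{NULL} skips
#'   writing.
#' @return the \code{"netmug_result"}, invisibly, with \code{report} printed.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  has_sim <- !is.null(config$simulation)
  has_inp <- !is.null(config$inputs)
  if (has_sim == has_inp)
    stop("config must contain exactly one of 'simulation' or 'inputs'")
  seed <- config$seed

  truth <- NULL
  if (has_sim) {
    sim_args <- config$simulation
    sim_args$seed <- derive_seed(seed, 10L)
    d <- simulate_multiview(do.call(sim_config, sim_args))
    X <- d$X; Y <- d$Y; Z <- d$Z; truth <- d$labels
  } else {
    for (f in c("x", "y", "z"))
      if (is.null(config$inputs[[f]])) stop("missing input path: ", f)
    X <- read_view_tsv(config$inputs$x)
    Y <- read_view_tsv(config$inputs$y)
    Z <- read_vector_tsv(config$inputs$z)
    if (!is.null(config$inputs$truth))
      truth <- read_vector_tsv(config$inputs$truth)
    if (!identical(rownames(X), rownames(Y)) ||
        !identical(rownames(X), names(Z)))
      stop("sample ids of X, Y and Z do not match")
  }

  smcca_cfg <- do.call(smcca_config, as.list(config$smcca))
  res <- run_netmug(X, Y, Z, truth = truth, smcca_cfg = smcca_cfg,
                    cut_height = config$cut_height %||% 0.999,
                    deep_split = config$deep_split %||% 1L,
                    min_cluster_size = config$min_cluster_size %||% 20L,
                    isn_include_phenotype = config$isn_phenotype %||% TRUE,
                    seed = seed)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (has_sim) write_multiview(d, out_dir)
    write_pipeline_artifacts(res, out_dir,
                             top_fraction = config$top_fraction %||% 0.01)
  }
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
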
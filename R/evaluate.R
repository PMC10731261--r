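#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie chance-corrected pair-agreement index computed from the
#' contingency table: \code{(sum_ij C(n_ij,2) - E) / (max - E)} where E is
#' the expectation under random partitions with fixed margins. Equals 1 for
#' identical partitions (up to label renaming) and is about 0 for independent
#' ones. When both partitions are trivial (the normalizer vanishes), the
#' index is defined as 1 if they are identical and 0 otherwise.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return numeric scalar in [-1, 1].
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("label vectors differ in length")
  n <- length(labels_a)
  if (n < 2L) stop("need at least 2 items")
  tab <- table(labels_a, labels_b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  total <- choose2(n)
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  if (abs(max_index - expected) < .Machine$double.eps * total) {
    # both partitions trivial: identical up to renaming iff the contingency
    # table has exactly one nonzero per row and per column
    one_to_one <- all(rowSums(tab > 0) == 1L) && all(colSums(tab > 0) == 1L) &&
      nrow(tab) == ncol(tab)
    return(if (one_to_one) 1 else 0)
  }
  (sum_ij - expected) / (max_index - expected)
}

#' Kruskal-Wallis rank test of a variable across groups
#'
#' Rank-based H statistic with ties correction and p-value from the
#' chi-squared approximation with C-1 degrees of freedom. All values
#' identical yields H = 0, p = 1.
#'
#' @param values numeric vector.
#' @param groups group labels of the same length; at least 2 non-empty
#'   groups.
#' @return list with \code{statistic} and \code{pvalue}.
#' @export
kruskal_wallis <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (stats::sd(values) == 0) return(list(statistic = 0, pvalue = 1))
  kt <- stats::kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), pvalue = kt$p.value)
}

#' Evaluate a clustering against ground truth and the phenotype
#'
#' @param labels derived cluster labels (1..C).
#' @param truth optional ground-truth labels for the adjusted Rand index.
#' @param z optional phenotype for the Kruskal-Wallis association.
#' @return list of class \code{"evaluation_report"}: \code{ari} (or NA),
#'   \code{kw_statistic}, \code{kw_pvalue} (or NA), \code{n_clusters},
#'   \code{cluster_sizes}.
#' @export
evaluate_clustering <- function(labels, truth = NULL, z = NULL) {
  sizes <- as.integer(table(labels[labels > 0L]))
  rep <- list(ari = if (is.null(truth)) NA_real_
                    else adjusted_rand_index(labels, truth),
              kw_statistic = NA_real_, kw_pvalue = NA_real_,
              n_clusters = length(sizes), cluster_sizes = sizes)
  if (!is.null(z) && length(unique(labels)) >= 2L) {
    kw <- kruskal_wallis(z, labels)
    rep$kw_statistic <- kw$statistic
    rep$kw_pvalue <- kw$pvalue
  }
  structure(rep, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: %d clusters (sizes %s)\n", x$n_clusters,
              paste(x$cluster_sizes, collapse = "/")))
  if (!is.na(x$ari)) cat(sprintf("  ARI vs truth:    %.4f\n", x$ari))
  if (!is.na(x$kw_pvalue))
    cat(sprintf("  Kruskal-Wallis:  H = %.2f, p = %.3g\n",
                x$kw_statistic, x$kw_pvalue))
  invisible(x)
}
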
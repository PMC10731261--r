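#' Adaptive cluster detection on a dendrogram (dynamic hybrid tree cut)
#'
#' Port of the Dynamic Hybrid branch-decomposition algorithm. Merges of the
#' dendrogram are processed bottom-up below a reference cut height; growing
#' branches are recognized as clusters when they are large enough
#' (\code{min_cluster_size}), internally tight (core scatter below a limit)
#' and separated from their surroundings (gap between the joining height and
#' the core scatter above a limit). \code{deep_split} (0-4) moves both limits
#' jointly: higher values admit smaller, less separated branches and hence
#' more clusters. Points not claimed by any cluster core are assigned
#' afterwards to the cluster with the smallest mean dissimilarity (a PAM-like
#' stage), capped at the cut height.
#'
#' @param tree an \code{hclust} object (monotone linkage, e.g. ward.D2).
#' @param D the dissimilarity used to build \code{tree} (matrix or
#'   \code{dist}).
#' @param deep_split integer 0-4; 1 (default) favors fewer, larger clusters.
#' @param min_cluster_size minimum branch size to qualify as a cluster
#'   (default 20, capped at n/2 so small inputs remain clusterable).
#' @param cut_height maximum joining height considered; default is 99% of the
#'   range between the 5th-percentile merge height and the top merge height.
#' @param pam_stage assign leftover points to the nearest cluster
#'   (default TRUE). With \code{FALSE} such points keep label 0.
#' @param max_pam_dist maximum mean dissimilarity for the PAM-like
#'   assignment; defaults to \code{cut_height}.
#' @return integer labels of length n: 1..C (cluster ids by decreasing size),
#'   0 for unassigned points (only when \code{pam_stage = FALSE} or a point
#'   exceeds \code{max_pam_dist}). If no branch qualifies, all points are
#'   placed in a single cluster.
#' @export
dynamic_tree_cut <- function(tree, D, deep_split = 1L, min_cluster_size = 20L,
                             cut_height = NULL, pam_stage = TRUE,
                             max_pam_dist = NULL) {
  stopifnot(inherits(tree, "hclust"))
  if (!deep_split %in% 0:4) stop("deep_split must be an integer in 0..4")
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 2L || length(tree$height) < 1L) stop("empty or trivial tree")
  stopifnot(length(tree$height) == n - 1L)
  min_cluster_size <- max(2L, min(as.integer(min_cluster_size), n %/% 2L))

  heights <- tree$height
  n_merge <- length(heights)
  ref_height <- heights[max(1L, round(0.05 * n_merge))]
  top_height <- max(heights)
  if (is.null(cut_height))
    cut_height <- 0.99 * (top_height - ref_height) + ref_height
  if (is.null(max_pam_dist)) max_pam_dist <- cut_height
  # degenerate tree (e.g. all points identical): no scale to split on
  if (top_height - ref_height < 1e-12) return(rep(1L, n))

  mcs_grid <- c(0.64, 0.73, 0.82, 0.91, 0.95)
  max_core_scatter <- mcs_grid[deep_split + 1L]
  min_gap <- (1 - max_core_scatter) * 3 / 4
  max_abs_scatter <- ref_height + max_core_scatter * (cut_height - ref_height)
  min_abs_gap <- min_gap * (cut_height - ref_height)

  core_size <- function(sz) {
    base <- min_cluster_size / 2 + 1
    if (base < sz) min(sz, as.integer(base + sqrt(sz - base))) else sz
  }
  # mean distance of a core member to the other core members; the core is
  # the earliest-joining part of the branch
  core_scatter <- function(members) {
    cs <- core_size(length(members))
    if (cs < 2L) return(0)
    core <- members[seq_len(cs)]
    sum(D[core, core]) / (cs * (cs - 1L))
  }
  qualifies <- function(members, attach_h) {
    if (length(members) < min_cluster_size) return(FALSE)
    sc <- core_scatter(members)
    sc < max_abs_scatter && (attach_h - sc) > min_abs_gap
  }

  branches <- vector("list", 2L * n_merge)
  n_branch <- 0L
  merge_branch <- integer(n_merge)  # branch produced by each processed merge
  new_branch <- function(b) {
    n_branch <<- n_branch + 1L
    branches[[n_branch]] <<- b
    n_branch
  }
  child <- function(code, h) {
    # merge-table child: negative = singleton index, positive = earlier merge
    if (code < 0L)
      list(kind = "singleton", members = -code)
    else {
      id <- merge_branch[code]
      c(branches[[id]], list(kind = branches[[id]]$type, id = id))
    }
  }

  root_ids <- integer(0)  # branches whose parent merge lies above cut_height
  for (mrg in seq_len(n_merge)) {
    h <- heights[mrg]
    if (h > cut_height) {
      # this merge is ignored; its already-built branch children become roots
      # (children that were themselves ignored merges contributed theirs)
      for (code in tree$merge[mrg, ]) {
        if (code > 0L && merge_branch[code] != 0L)
          root_ids <- c(root_ids, merge_branch[code])
      }
      merge_branch[mrg] <- 0L
      next
    }
    b1 <- child(tree$merge[mrg, 1L], h)
    b2 <- child(tree$merge[mrg, 2L], h)
    kinds <- c(b1$kind, b2$kind)
    if (all(kinds == "singleton")) {
      merge_branch[mrg] <- new_branch(list(type = "basic",
                                           members = c(b1$members, b2$members)))
    } else if (any(kinds == "singleton")) {
      s <- if (b1$kind == "singleton") b1 else b2
      br <- if (b1$kind == "singleton") b2 else b1
      if (br$kind == "basic") {
        branches[[br$id]]$members <- c(br$members, s$members)
      } else {
        branches[[br$id]]$stragglers <- c(br$stragglers, s$members)
      }
      merge_branch[mrg] <- br$id
    } else if (b1$kind == "basic" && b2$kind == "basic") {
      sizes <- c(length(b1$members), length(b2$members))
      sm <- if (sizes[1] <= sizes[2]) b1 else b2
      lg <- if (sizes[1] <= sizes[2]) b2 else b1
      if (qualifies(sm$members, h)) {
        # smaller branch stands on its own: the merge node becomes a
        # composite; the larger side is kept if it also qualifies
        clusters <- list(sm$members)
        stragglers <- integer(0)
        if (qualifies(lg$members, h)) clusters <- c(clusters, list(lg$members))
        else stragglers <- lg$members
        merge_branch[mrg] <- new_branch(list(
          type = "composite", members = c(lg$members, sm$members),
          clusters = clusters, stragglers = stragglers))
      } else {
        # smaller branch fails: absorb it into the larger one
        branches[[lg$id]]$members <- c(lg$members, sm$members)
        merge_branch[mrg] <- lg$id
      }
    } else if (all(kinds == "composite")) {
      merge_branch[mrg] <- new_branch(list(
        type = "composite", members = c(b1$members, b2$members),
        clusters = c(b1$clusters, b2$clusters),
        stragglers = c(b1$stragglers, b2$stragglers)))
    } else {
      ba <- if (b1$kind == "basic") b1 else b2
      co <- if (b1$kind == "basic") b2 else b1
      upd <- branches[[co$id]]
      if (qualifies(ba$members, h)) upd$clusters <- c(upd$clusters, list(ba$members))
      else upd$stragglers <- c(upd$stragglers, ba$members)
      upd$members <- c(upd$members, ba$members)
      branches[[co$id]] <- upd
      merge_branch[mrg] <- co$id
    }
  }
  if (merge_branch[n_merge] != 0L)
    root_ids <- c(root_ids, merge_branch[n_merge])
  root_ids <- unique(root_ids)

  clusters <- list()
  for (id in root_ids) {
    b <- branches[[id]]
    if (b$type == "composite") clusters <- c(clusters, b$clusters)
    else if (qualifies(b$members, cut_height))
      clusters <- c(clusters, list(b$members))
  }
  if (length(clusters) == 0L) return(rep(1L, n))

  ord <- order(-vapply(clusters, length, 1L),
               vapply(clusters, min, 1L))
  clusters <- clusters[ord]
  labels <- integer(n)
  for (ci in seq_along(clusters)) labels[clusters[[ci]]] <- ci

  if (pam_stage && any(labels == 0L)) {
    mean_d <- vapply(clusters,
                     function(m) rowMeans(D[, m, drop = FALSE]),
                     numeric(n))
    if (is.null(dim(mean_d))) mean_d <- matrix(mean_d, nrow = n)
    for (s in which(labels == 0L)) {
      best <- which.min(mean_d[s, ])
      if (mean_d[s, best] <= max_pam_dist) labels[s] <- best
    }
  }
  labels
}
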
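make_isns <- function(n = 8, r = 5, seed = 25) {
  set.seed(seed)
  individual_specific_networks(matrix(rnorm(n * r), n, r), rnorm(n))
}

test_that("mean ISN averages member networks entrywise", {
  isns <- make_isns()
  expect_equal(mean_isn(isns, 3), fold_edge_vector(isns$W[3, ], isns$node_ids))
  # two-sample average by hand
  expect_equal(mean_isn(isns, c(1, 2)),
               fold_edge_vector((isns$W[1, ] + isns$W[2, ]) / 2, isns$node_ids))
  # naive loop over all members
  ref <- Reduce(`+`, lapply(seq_len(nrow(isns$W)), function(s)
    fold_edge_vector(isns$W[s, ], isns$node_ids))) / nrow(isns$W)
  expect_equal(mean_isn(isns), ref, tolerance = 1e-12)
  expect_error(mean_isn(isns, integer(0)), "empty")
})

test_that("top-edge binarization keeps an exact ceiling count with ties", {
  M <- fold_edge_vector(c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1))  # r = 5, k = 10
  b <- binarize_top_edges(M, 0.2)
  expect_equal(b$n_retained, 2)
  expect_equal(sum(b$adjacency) / 2, 2)
  expect_equal(unname(b$adjacency[1, 2]), 1)  # weight 10
  expect_equal(unname(b$adjacency[1, 3]), 1)  # weight 9
  # all-equal weights: tie rule still yields ceiling(f * k) edges
  b2 <- binarize_top_edges(fold_edge_vector(rep(1, 10)), 0.5)
  expect_equal(sum(b2$adjacency) / 2, 5)
  # fraction 1 keeps the complete graph
  b3 <- binarize_top_edges(M, 1)
  expect_equal(sum(b3$adjacency) / 2, 10)
  expect_true(all(diag(b3$adjacency) == 0))
  expect_error(binarize_top_edges(M, 0), "fraction")
})

test_that("largest connected component follows size and tie rules", {
  # two disjoint triangles: tie broken by smallest node index
  A <- matrix(0, 6, 6)
  for (e in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)))
    A[e[1], e[2]] <- A[e[2], e[1]] <- 1
  lcc <- largest_connected_component(A)
  expect_identical(lcc$nodes, 1:3)
  # path of 4 plus an isolated node
  B <- matrix(0, 5, 5)
  for (e in list(c(1, 2), c(2, 3), c(3, 4)))
    B[e[1], e[2]] <- B[e[2], e[1]] <- 1
  lcc2 <- largest_connected_component(B)
  expect_identical(lcc2$nodes, 1:4)
  expect_equal(nrow(lcc2$edges), 3)
  # random graphs against a BFS oracle
  set.seed(26)
  for (rep in 1:10) {
    n <- 12
    A <- matrix(rbinom(n * n, 1, 0.12), n, n)
    A[lower.tri(A, diag = TRUE)] <- 0
    A <- A + t(A)
    comp <- oracle_components(A)
    big <- which.max(tabulate(comp))
    expect_identical(largest_connected_component(A)$nodes,
                     which(comp == big))
  }
})

test_that("filtration curve matches hand-enumerated toy values", {
  # 4 nodes, weights ab=3, bc=2, cd=1
  M <- matrix(0, 4, 4)
  M[1, 2] <- M[2, 1] <- 3
  M[2, 3] <- M[3, 2] <- 2
  M[3, 4] <- M[4, 3] <- 1
  fc <- filtration_curve(M, c(0.5, 1.5, 2.5, 3.5))
  # t=0.5: full path (3 edges, 4 nodes) -> 1.5; t=1.5: {ab,bc} -> 4/3;
  # t=2.5: {ab} -> 1; t=3.5: empty -> 0
  expect_equal(fc$values, c(1.5, 4 / 3, 1, 0))
  # complete graph of unit weights
  K4 <- matrix(1, 4, 4); diag(K4) <- 0
  expect_equal(filtration_curve(K4, c(0.5, 1.5))$values, c(3, 0))
  # below the minimum weight the value is 2k/r of the full graph
  set.seed(27)
  W <- abs(matrix(rnorm(36), 6, 6)); W <- W + t(W); diag(W) <- 0
  v0 <- filtration_curve(W, min(W[upper.tri(W)]) / 2)$values
  expect_equal(v0, 2 * 15 / 6)
  expect_error(filtration_curve(M, c(2, 1)), "sorted|unsorted|TRUE")
})

test_that("binary networks and LCC node lists round-trip through their writers", {
  M <- fold_edge_vector(c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1),
                        node_ids = paste0("g", 1:5))
  b <- binarize_top_edges(M, 0.3)
  p1 <- tempfile(fileext = ".tsv")
  write_binary_network(b, p1)
  edges <- read.delim(p1)
  expect_equal(nrow(edges), b$n_retained)
  expect_true(all(edges$node_i %in% b$node_ids))
  lcc <- largest_connected_component(b)
  p2 <- tempfile(fileext = ".txt")
  write_lcc_nodes(lcc, p2)
  expect_identical(readLines(p2), lcc$node_ids)
  unlink(c(p1, p2))
})

test_that("per-cluster curves aggregate pointwise", {
  isns <- make_isns(n = 9, r = 4)
  labels <- rep(1:3, each = 3)
  thr <- default_threshold_grid(isns, 10)
  expect_equal(length(thr), 10)
  expect_true(!is.unsorted(thr))
  out <- curves_by_cluster(isns, labels, thr)
  expect_identical(nrow(out), 30L)
  # recompute one cluster by hand
  rows <- which(labels == 2)
  curves <- sapply(rows, function(s)
    filtration_curve(fold_edge_vector(isns$W[s, ]), thr)$values)
  expect_equal(out$mean[out$cluster == 2], rowMeans(curves))
  expect_equal(out$sd[out$cluster == 2], apply(curves, 1, sd))
  # single-member cluster: sd is 0, mean is that curve
  out1 <- curves_by_cluster(isns, c(1, rep(2, 8)), thr)
  expect_equal(out1$sd[out1$cluster == 1], rep(0, 10))
  expect_equal(out1$mean[out1$cluster == 1],
               filtration_curve(fold_edge_vector(isns$W[1, ]), thr)$values)
})
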
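test_that("standardize centers and scales columns (n-1 denominator)", {
  expect_equal(unname(standardize(matrix(c(1, 2, 3)))), matrix(c(-1, 0, 1)),
               ignore_attr = TRUE)
  set.seed(1)
  M <- matrix(rnorm(250), 50, 5)
  S <- standardize(M)
  expect_lt(max(abs(colMeans(S))), 1e-12)
  expect_equal(unname(apply(S, 2, sd)), rep(1, 5), tolerance = 1e-12)
  expect_equal(unname(standardize(S)), unname(S), tolerance = 1e-12)
  M[, 3] <- 7
  colnames(M) <- paste0("f", 1:5)
  expect_error(standardize(M), "f3")
})

test_that("without sparsity or supervision the fit matches the rank-1 SVD", {
  set.seed(2)
  for (rep in 1:10) {
    X <- standardize(matrix(rnorm(30 * 5), 30, 5))
    Y <- standardize(matrix(rnorm(30 * 4), 30, 4))
    cfg <- smcca_config(c1 = sqrt(5), c2 = sqrt(4), w2 = 0, w3 = 0)
    fit <- smcca_fit(X, Y, NULL, cfg)
    sv <- svd(crossprod(X, Y))
    expect_gte(abs(sum(fit$a * sv$u[, 1])), 0.999)
    expect_gte(abs(sum(fit$b * sv$v[, 1])), 0.999)
    expect_equal(fit$objective_value, sv$d[1], tolerance = 1e-6)
  }
})

test_that("p = q = 1 reduces to the sign choice maximizing the objective", {
  set.seed(3)
  x <- standardize(rnorm(20)); y <- standardize(-x + rnorm(20, sd = 0.1))
  z <- standardize(rnorm(20))
  fit <- smcca_fit(matrix(x), matrix(y), z, smcca_config(c1 = 1, c2 = 1))
  expect_true(all(abs(c(fit$a, fit$b)) == 1))
  obj <- function(a, b) a * b * sum(x * y) + a * sum(x * z) + b * sum(y * z)
  best <- max(obj(1, 1), obj(1, -1), obj(-1, 1), obj(-1, -1))
  expect_equal(fit$objective_value, best)
})

test_that("sparse supervised fit matches a brute-force grid search", {
  set.seed(4)
  X <- standardize(matrix(rnorm(30 * 3), 30, 3))
  Y <- standardize(matrix(rnorm(30 * 3), 30, 3))
  Z <- standardize(rnorm(30))
  fit <- smcca_fit(X, Y, Z, smcca_config(c1 = 1.2, c2 = 1.2))
  ref <- oracle_smcca_grid(crossprod(X, Y), drop(crossprod(X, Z)),
                           drop(crossprod(Y, Z)), 1.2, 1.2)
  expect_equal(fit$objective_value, ref, tolerance = 1e-3)
  expect_gte(fit$objective_value, ref - 1e-3)  # never worse than the grid
})

test_that("constraints hold at the solution", {
  set.seed(5)
  X <- standardize(matrix(rnorm(40 * 8), 40, 8))
  Y <- standardize(matrix(rnorm(40 * 6), 40, 6))
  Z <- standardize(rnorm(40))
  for (c1 in c(1, 1.5, 2.5)) {
    fit <- smcca_fit(X, Y, Z, smcca_config(c1 = c1, c2 = 1.8))
    expect_equal(sqrt(sum(fit$a^2)), 1, tolerance = 1e-8)
    expect_equal(sqrt(sum(fit$b^2)), 1, tolerance = 1e-8)
    expect_lte(sum(abs(fit$a)), c1 + 1e-6)
    expect_lte(sum(abs(fit$b)), 1.8 + 1e-6)
  }
})

test_that("objective is non-decreasing across alternating iterations", {
  set.seed(6)
  X <- standardize(matrix(rnorm(25 * 6), 25, 6))
  Y <- standardize(matrix(rnorm(25 * 5), 25, 5))
  Z <- standardize(rnorm(25))
  cfg <- smcca_config(c1 = 1.5, c2 = 1.5)
  # re-run the alternating updates manually and track the objective
  XtY <- crossprod(X, Y); XtZ <- drop(crossprod(X, Z)); YtZ <- drop(crossprod(Y, Z))
  obj <- function(a, b) drop(crossprod(a, XtY %*% b)) + sum(a * XtZ) + sum(b * YtZ)
  prev <- -Inf
  for (it in 1:15) {
    fit <- suppressWarnings(
      smcca_fit(X, Y, Z, smcca_config(c1 = 1.5, c2 = 1.5, max_iter = it)))
    cur <- obj(fit$a, fit$b)
    expect_gte(cur, prev - 1e-10)
    prev <- cur
  }
})

test_that("rescaling Z leaves the fitted weights unchanged after standardization", {
  set.seed(7)
  X <- matrix(rnorm(30 * 4), 30, 4); Y <- matrix(rnorm(30 * 4), 30, 4)
  Z <- rnorm(30)
  cfg <- smcca_config(c1 = 1.5, c2 = 1.5)
  f1 <- smcca_fit(standardize(X), standardize(Y), standardize(Z), cfg)
  f2 <- smcca_fit(standardize(X), standardize(Y), standardize(13.7 * Z), cfg)
  expect_equal(f1$a, f2$a, tolerance = 1e-10)
  expect_equal(f1$b, f2$b, tolerance = 1e-10)
})

test_that("tightening c1 never makes the weight vector denser", {
  set.seed(8)
  X <- standardize(matrix(rnorm(40 * 10), 40, 10))
  Y <- standardize(matrix(rnorm(40 * 10), 40, 10))
  Z <- standardize(rnorm(40))
  nnz <- sapply(c(3, 2.5, 2, 1.5, 1.2, 1), function(c1) {
    fit <- smcca_fit(X, Y, Z, smcca_config(c1 = c1, c2 = 2))
    sum(abs(fit$a) > 1e-8)
  })
  expect_true(all(diff(nnz) <= 0))
})

test_that("infeasible sparsity bounds are rejected", {
  X <- standardize(matrix(rnorm(20 * 4), 20, 4))
  expect_error(smcca_fit(X, X, NULL, smcca_config(c1 = 3, c2 = 1.1)),
               "sqrt")
  expect_error(smcca_config(c1 = 0.5), ">= 1")
})

test_that("similarity layer follows the absolute outer product", {
  S <- similarity_from_weights(c(1, -0.5))
  expect_equal(S, matrix(c(1, 0.5, 0.5, 0.25), 2, 2))
})

test_that("subsampled similarity equals a naive loop re-implementation", {
  set.seed(9)
  X <- matrix(rnorm(40 * 6), 40, 6); Y <- matrix(rnorm(40 * 6), 40, 6)
  Z <- rnorm(40)
  cfg <- smcca_config(c1 = 1.5, c2 = 1.5, n_subsamples = 5,
                      subsample_prop_x = 0.7, subsample_prop_y = 0.7,
                      seed = 123)
  sim <- subsampled_similarity(X, Y, Z, cfg)
  ref <- oracle_subsampled_similarity(X, Y, Z, cfg)
  expect_equal(unname(sim$S), ref, tolerance = 1e-12)
  expect_true(isSymmetric(sim$S))
  expect_true(all(sim$S >= 0 & sim$S <= 1))
  expect_equal(max(sim$S), 1)
})

test_that("module detection honors the cut height and the cross-view rule", {
  # block-diagonal similarity: two cross-view blocks, one X-only block
  ids <- c(paste0("x", 1:6), paste0("y", 1:4))
  S <- diag(10)
  blocks <- list(c(1, 2, 7, 8), c(3, 4, 9, 10), c(5, 6))
  for (b in blocks) S[b, b] <- 0.9
  diag(S) <- 1
  dimnames(S) <- list(ids, ids)
  sim <- structure(list(S = S, feature_ids = ids,
                        view_of = rep(c("X", "Y"), c(6, 4))),
                   class = "similarity_matrix")
  mods <- detect_modules(sim, cut_height = 0.5)
  expect_length(mods, 2)  # X-only block discarded
  got <- lapply(mods, `[[`, "member_indices")
  expect_setequal(lapply(got, sort), lapply(blocks[1:2], sort))
  # identity similarity: all singletons, nothing survives
  sim0 <- structure(list(S = diag(10), feature_ids = ids,
                         view_of = rep(c("X", "Y"), c(6, 4))),
                    class = "similarity_matrix")
  expect_length(detect_modules(sim0, cut_height = 0.9), 0)
})

test_that("select_features unions module members without duplicates", {
  expect_identical(select_features(list(), p = 5),
                   list(x_indices = integer(0), y_indices = integer(0)))
  mods <- list(list(member_indices = c(1L, 3L, 7L)),
               list(member_indices = c(3L, 6L, 7L)))
  sel <- select_features(mods, p = 5)
  expect_identical(sel$x_indices, c(1L, 3L))
  expect_identical(sel$y_indices, c(1L, 2L))
})

test_that("cross-validation picks a grid pair and is deterministic", {
  set.seed(10)
  n <- 60
  u <- rnorm(n)
  X <- cbind(sapply(1:10, function(i) u + rnorm(n)),
             matrix(rnorm(n * 90), n, 90))
  Y <- cbind(sapply(1:10, function(i) u + rnorm(n)),
             matrix(rnorm(n * 90), n, 90))
  Z <- u + rnorm(n)
  single <- cross_validate_sparsity(X, Y, Z, grid_c1 = 2, grid_c2 = 2,
                                    seed = 1)
  expect_equal(c(single$c1, single$c2), c(2, 2))
  cv1 <- cross_validate_sparsity(X, Y, Z, grid_c1 = c(2, 10),
                                 grid_c2 = c(2, 10), seed = 1)
  cv2 <- cross_validate_sparsity(X, Y, Z, grid_c1 = c(2, 10),
                                 grid_c2 = c(2, 10), seed = 1)
  expect_identical(cv1$grid, cv2$grid)
  # sparse signal + many noise features: some sparse cell beats the
  # no-sparsity corner in held-out canonical correlation
  corner <- cv1$grid$mean_cor[cv1$grid$c1 == 10 & cv1$grid$c2 == 10]
  expect_gte(max(cv1$grid$mean_cor), corner)
})
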
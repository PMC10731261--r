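test_that("config invariants are enforced", {
  expect_error(sim_config(n_features_per_view = 10, n_noise = 5, n_corr = 3,
                          n_clust = 3), "must equal")
  expect_error(sim_config(cluster_multipliers = c(1, 2)), "length n_clusters")
  expect_error(sim_config(corr_cov_range = c(0.5, 1.0)), "< 1")
  expect_error(sim_config(corr_cov_range = c(0.8, 0.5)), "ordered")
})

test_that("default benchmark design has the stated shapes and balanced labels", {
  d <- simulate_multiview(sim_config(seed = 42))
  expect_identical(dim(d$X), c(1000L, 1000L))
  expect_identical(dim(d$Y), c(1000L, 1000L))
  expect_length(d$Z, 1000)
  expect_identical(sort(as.integer(table(d$labels))), c(333L, 333L, 334L))
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- sim_config(n_samples = 50, n_features_per_view = 20, n_noise = 12,
                    n_corr = 4, n_clust = 4, seed = 99)
  d1 <- simulate_multiview(cfg)
  d2 <- simulate_multiview(cfg)
  expect_identical(d1$X, d2$X)
  expect_identical(d1$Y, d2$Y)
  expect_identical(d1$Z, d2$Z)
  expect_identical(d1$labels, d2$labels)
})

test_that("unbalanced n is split into near-equal clusters (sizes differ <= 1)", {
  for (n in c(100, 101, 103)) {
    d <- simulate_multiview(sim_config(n_samples = n, n_features_per_view = 6,
                                       n_noise = 2, n_corr = 2, n_clust = 2,
                                       seed = n))
    expect_lte(diff(range(table(d$labels))), 1)
  }
})

test_that("cross-view latent correlation matches the generative covariance", {
  # one corr pair, no mixing, large n: empirical correlation ~ drawn rho
  cfg <- sim_config(n_samples = 20000, n_features_per_view = 3, n_noise = 1,
                    n_corr = 1, n_clust = 1, corr_cov_range = c(0.7, 0.7),
                    cluster_multipliers = c(1, 1, 1), mixing_range = NULL,
                    seed = 5)
  d <- simulate_multiview(cfg)
  expect_equal(cor(d$X[, "X_corr_1"], d$Y[, "Y_corr_1"]), 0.7,
               tolerance = 0.02)
  # clust latents (multipliers disabled) land in their own covariance range
  r_clust <- cor(d$X[, "X_clust_1"], d$Y[, "Y_clust_1"])
  expect_gt(r_clust, 0.78)
})

test_that("cluster multipliers scale the per-cluster sd of clust latents 1:2:3", {
  cfg <- sim_config(n_samples = 9000, n_features_per_view = 2, n_noise = 0,
                    n_corr = 1, n_clust = 1, mixing_range = NULL, seed = 6)
  d <- simulate_multiview(cfg)
  sds <- tapply(d$X[, "X_clust_1"], d$labels, sd)
  expect_equal(as.vector(sds / sds[1]), c(1, 2, 3), tolerance = 0.08)
})

test_that("noise is uncorrelated with the phenotype at the 1/sqrt(n) scale", {
  cfg <- sim_config(n_samples = 4000, n_features_per_view = 20, n_noise = 18,
                    n_corr = 1, n_clust = 1, seed = 7)
  d <- simulate_multiview(cfg)
  noise_cols <- grep("noise", colnames(d$X))
  cors <- abs(cor(d$X[, noise_cols], d$Z))
  expect_lt(mean(cors), 3 / sqrt(4000))
})

test_that("planted phenotype shifts are detectable by Kruskal-Wallis", {
  cfg <- sim_config(n_samples = 100, n_features_per_view = 6, n_noise = 2,
                    n_corr = 2, n_clust = 2, seed = 8)
  d <- simulate_multiview(cfg)
  kw <- kruskal_wallis(d$Z, d$labels)
  expect_lt(kw$pvalue, 0.05)
})

test_that("feature roles are recoverable from feature ids", {
  d <- simulate_multiview(sim_config(n_samples = 10, n_features_per_view = 6,
                                     n_noise = 2, n_corr = 2, n_clust = 2,
                                     seed = 9))
  expect_identical(as.character(feature_roles(colnames(d$X))),
                   c("corr", "corr", "clust", "clust", "noise", "noise"))
})
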
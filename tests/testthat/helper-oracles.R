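# Independent oracle implementations used to cross-check the package's
# primary routines. These are deliberately naive (loops, closed forms,
# exhaustive search) and share no code with the implementation under test.

# -- pairwise-correlation edge scores, recomputed entry by entry -------------
oracle_global_edges <- function(V, Z) {
  r <- ncol(V)
  E <- matrix(NA_real_, r, r)
  for (i in seq_len(r - 1)) for (j in (i + 1):r) {
    e <- cor(V[, i], V[, j]) + cor(V[, i], Z) + cor(V[, j], Z)
    E[i, j] <- e; E[j, i] <- e
  }
  E
}

# -- similarity matrix by a naive subsample loop -----------------------------
oracle_subsampled_similarity <- function(X, Y, Z, cfg) {
  p <- ncol(X); q <- ncol(Y)
  set.seed(cfg$seed)
  kx <- ceiling(cfg$subsample_prop_x * p)
  ky <- ceiling(cfg$subsample_prop_y * q)
  Zs <- netmug::standardize(Z)
  total <- matrix(0, p + q, p + q)
  for (run in seq_len(cfg$n_subsamples)) {
    ix <- sort(sample.int(p, kx)); iy <- sort(sample.int(q, ky))
    cfg_run <- cfg
    cfg_run$c1 <- if (is.null(cfg$c1)) NULL else max(1, min(cfg$c1, sqrt(kx)))
    cfg_run$c2 <- if (is.null(cfg$c2)) NULL else max(1, min(cfg$c2, sqrt(ky)))
    fit <- netmug::smcca_fit(netmug::standardize(X[, ix, drop = FALSE]),
                             netmug::standardize(Y[, iy, drop = FALSE]),
                             Zs, cfg_run)
    ab <- c(fit$a, fit$b)
    full <- numeric(p + q)
    layer <- matrix(0, p + q, p + q)
    idx <- c(ix, p + iy)
    for (u in seq_along(idx)) for (v in seq_along(idx))
      layer[idx[u], idx[v]] <- abs(ab[u] * ab[v])
    total <- total + layer
  }
  S <- total / cfg$n_subsamples
  S / max(S)
}

# -- brute-force SmCCA on 3+3 variables over gridded unit spheres ------------
# 2-degree angular grid on each sphere, restricted to l1-feasible points.
oracle_sphere_grid <- function(step_deg = 2) {
  th <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  ph <- seq(0, 360 - step_deg, by = step_deg) * pi / 180
  g <- expand.grid(th = th, ph = ph)
  cbind(sin(g$th) * cos(g$ph), sin(g$th) * sin(g$ph), cos(g$th))
}

oracle_sphere_window <- function(center_th, center_ph, half, step) {
  th <- seq(center_th - half, center_th + half, by = step)
  ph <- seq(center_ph - half, center_ph + half, by = step)
  g <- expand.grid(th = th, ph = ph)
  list(xyz = cbind(sin(g$th) * cos(g$ph), sin(g$th) * sin(g$ph), cos(g$th)),
       th = g$th, ph = g$ph)
}

oracle_smcca_grid <- function(XtY, XtZ, YtZ, c1, c2, w = c(1, 1, 1),
                              step_deg = 2) {
  score <- function(A, B) {
    # objective = a' (w1 XtY) b + w2 a'XtZ + w3 b'YtZ over all grid pairs
    G <- A %*% (w[1] * XtY) %*% t(B)
    G <- G + matrix(w[2] * A %*% XtZ, nrow(A), nrow(B))
    G <- G + matrix(w[3] * B %*% YtZ, nrow(A), nrow(B), byrow = TRUE)
    G
  }
  # global coarse scan over both unit spheres (l1-feasible points only)
  th <- seq(0, pi, length.out = ceiling(180 / step_deg))
  ph <- seq(0, 2 * pi, length.out = ceiling(360 / step_deg))
  g <- expand.grid(th = th, ph = ph)
  P <- cbind(sin(g$th) * cos(g$ph), sin(g$th) * sin(g$ph), cos(g$th))
  fa <- rowSums(abs(P)) <= c1
  fb <- rowSums(abs(P)) <= c2
  G <- score(P[fa, , drop = FALSE], P[fb, , drop = FALSE])
  idx <- which(G == max(G), arr.ind = TRUE)[1, ]
  besta <- c(g$th[fa][idx[1]], g$ph[fa][idx[1]])
  bestb <- c(g$th[fb][idx[2]], g$ph[fb][idx[2]])
  best <- max(G)
  # local refinement around the coarse optimum (the l1 boundary cuts across
  # the angular grid, so the coarse scan alone can miss boundary optima)
  half <- 1.5 * step_deg * pi / 180
  for (stage in 1:3) {
    step <- half / 25
    wa <- oracle_sphere_window(besta[1], besta[2], half, step)
    wb <- oracle_sphere_window(bestb[1], bestb[2], half, step)
    ka <- rowSums(abs(wa$xyz)) <= c1
    kb <- rowSums(abs(wb$xyz)) <= c2
    if (!any(ka) || !any(kb)) break
    G <- score(wa$xyz[ka, , drop = FALSE], wb$xyz[kb, , drop = FALSE])
    if (max(G) > best) {
      best <- max(G)
      idx <- which(G == best, arr.ind = TRUE)[1, ]
      besta <- c(wa$th[ka][idx[1]], wa$ph[ka][idx[1]])
      bestb <- c(wb$th[kb][idx[2]], wb$ph[kb][idx[2]])
    }
    half <- half / 10
  }
  best
}

# -- ward.D2 by a direct Lance-Williams recursion ----------------------------
oracle_ward_d2_heights <- function(D) {
  D2 <- as.matrix(D)^2
  n <- nrow(D2)
  active <- seq_len(n)
  size <- rep(1, n)
  heights <- numeric(0)
  while (length(active) > 1) {
    sub <- D2[active, active]
    diag(sub) <- Inf
    ij <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    a <- active[ij[1]]; b <- active[ij[2]]
    heights <- c(heights, sqrt(min(sub)))
    na <- size[a]; nb <- size[b]
    for (c in setdiff(active, c(a, b))) {
      nc <- size[c]
      D2[a, c] <- D2[c, a] <-
        ((na + nc) * D2[a, c] + (nb + nc) * D2[b, c] - nc * D2[a, b]) /
        (na + nb + nc)
    }
    size[a] <- na + nb
    active <- setdiff(active, b)
  }
  sort(heights)
}

# -- pair-agreement (Hubert-Arabie) ARI by explicit pair counting ------------
oracle_ari_pairs <- function(la, lb) {
  n <- length(la)
  n11 <- n10 <- n01 <- n00 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- la[i] == la[j]; sb <- lb[i] == lb[j]
    if (sa && sb) n11 <- n11 + 1
    else if (sa) n10 <- n10 + 1
    else if (sb) n01 <- n01 + 1
    else n00 <- n00 + 1
  }
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) return(if (n10 + n01 == 0) 1 else 0)
  2 * (n11 * n00 - n10 * n01) / den
}

# all set partitions of n items as label vectors
oracle_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in oracle_partitions(n - 1)) {
    k <- max(p)
    for (g in seq_len(k + 1)) out[[length(out) + 1]] <- c(p, g)
  }
  out
}

# -- textbook Kruskal-Wallis H with ties correction --------------------------
oracle_kw_h <- function(values, groups) {
  rk <- rank(values)
  N <- length(values)
  groups <- factor(groups)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(rk, groups, function(r) length(r) * mean(r)^2)) -
    3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# -- BFS connected components ------------------------------------------------
oracle_components <- function(A) {
  n <- nrow(A)
  comp <- integer(n)
  cur <- 0
  for (s in seq_len(n)) {
    if (comp[s] != 0) next
    cur <- cur + 1
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(A[v, ] != 0 & comp == 0)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# -- small random fixtures ---------------------------------------------------
make_gaussian_blobs <- function(n_per = 20, dim = 5, sd = 0.1, sep = 10,
                                n_blobs = 3, seed = 1) {
  set.seed(seed)
  centers <- diag(sep, n_blobs, dim)
  X <- do.call(rbind, lapply(seq_len(n_blobs), function(b)
    matrix(rnorm(n_per * dim, sd = sd), n_per, dim) +
      matrix(centers[b, ], n_per, dim, byrow = TRUE)))
  list(X = X, labels = rep(seq_len(n_blobs), each = n_per))
}
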
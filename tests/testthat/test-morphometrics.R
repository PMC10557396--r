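# GPA, Procrustes distances, shape PCA, 2B-PLS, RV, permutation, extremes

test_that("GPA is invariant to similarity transforms and matches OPA", {
  set.seed(10)
  a <- matrix(stats::rnorm(36), 12)
  # transformed copy: distance zero with scaling on
  b <- 2.5 * a %*% t(rand_rotation()) + matrix(c(4, 1, -3), 12, 3,
                                               byrow = TRUE)
  g <- gpa(list(a, b), with_scaling = TRUE)
  expect_lt(max(g$distances), 1e-10)
  expect_lt(procrustes_distance(a, b), 1e-10)
  # mean of aligned configurations equals the reported mean
  expect_lt(max(abs(Reduce(`+`, g$aligned) / 2 - g$mean)), 1e-9)
  # unit centroid size of every aligned configuration
  expect_lt(max(abs(vapply(g$aligned, centroid_size, 0) - 1)), 1e-9)

  # without scaling: rigid invariance only
  b2 <- a %*% t(rand_rotation()) + 5
  expect_lt(procrustes_distance(a, b2, with_scaling = FALSE), 1e-10)
  expect_gt(procrustes_distance(a, 2 * a, with_scaling = FALSE), 0.1)

  # two-shape GPA against the closed-form pairwise OPA
  for (rep in 1:5) {
    x <- matrix(stats::rnorm(30), 10)
    y <- matrix(stats::rnorm(30), 10)
    g2 <- gpa(list(x, y), with_scaling = TRUE)
    d_pair <- sqrt(sum((g2$aligned[[1]] - g2$aligned[[2]])^2))
    expect_equal(d_pair, procrustes_distance(x, y), tolerance = 1e-6)
  }
  expect_error(gpa(list(matrix(0, 5, 3), a[1:5, ])), "degenerate")
  expect_error(procrustes_distance(a, a[1:5, ]), "equal k")
})

test_that("procrustes distance is a symmetric premetric", {
  set.seed(11)
  for (rep in 1:10) {
    x <- matrix(stats::rnorm(24), 8)
    y <- matrix(stats::rnorm(24), 8)
    z <- matrix(stats::rnorm(24), 8)
    expect_equal(procrustes_distance(x, y), procrustes_distance(y, x),
                 tolerance = 1e-12)
    expect_lte(procrustes_distance(x, z),
               procrustes_distance(x, y) + procrustes_distance(y, z) + 1e-9)
  }
  expect_equal(procrustes_distance(matrix(stats::rnorm(24), 8),
                                   matrix(stats::rnorm(24), 8)) >= 0, TRUE)
})

test_that("shape PCA finds rank, reconstructs, and recovers factors", {
  # data on a 2-plane of shape space -> exactly 2 meaningful eigenvalues
  # pre-aligned configurations lying exactly on a 2-plane of shape space
  planar <- factor_configs(20, k = 10, q = 2, sds = c(2, 1), noise = 0,
                           seed = 12)
  sp <- pca_shapes(planar, 1.0)
  expect_lt(length(sp$eigenvalues), 3)  # numerical rank 2

  # threshold 1.0: lossless reconstruction of every training shape
  for (i in c(1, 7)) {
    rec <- shape_from_scores(sp, sp$scores[i, ])
    expect_lt(max(abs(rec - planar[[i]])), 1e-6)
  }
  expect_error(pca_shapes(planar, 0), "threshold")
  expect_error(pca_shapes(planar, 1.5), "threshold")

  # 3-factor population at n = 100: dimension, variance and eigenvalues
  set.seed(13)
  base <- matrix(stats::rnorm(15 * 3), 15, 3) * 5
  modes <- lapply(1:3, function(j) matrix(stats::rnorm(15 * 3), 15, 3))
  zs <- matrix(stats::rnorm(300), 100, 3) %*% diag(c(3, 2, 1))
  cfgs <- lapply(1:100, function(i) {
    p <- base
    for (j in 1:3) p <- p + zs[i, j] * modes[[j]]
    p + matrix(stats::rnorm(45), 15, 3) * 0.01
  })
  sp3 <- pca_shapes(cfgs, 0.95)
  expect_equal(sp3$d, 3)
  expect_gt(sp3$cumulative[3], 0.99)
  # top-3 eigenvalues recover the generator-truth variances within 15%
  V <- vapply(modes, function(m) as.vector(t(m)), numeric(45))
  truth <- eigen(V %*% stats::cov(zs) %*% t(V), symmetric = TRUE,
                 only.values = TRUE)$values[1:3]
  expect_lt(max(abs(sp3$eigenvalues[1:3] - truth) / truth), 0.15)
})

test_that("2B-PLS matches a dense SVD of the cross-covariance", {
  set.seed(14)
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    X <- matrix(stats::rnorm(n * 6), n)
    Y <- matrix(stats::rnorm(n * 8), n)
    p <- two_block_pls(X, Y)
    # oracle: dense SVD of the cross-covariance of centered blocks
    Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
    sv <- svd(crossprod(Xc, Yc) / (n - 1))
    expect_equal(p$singular_values, sv$d[seq_along(p$singular_values)],
                 tolerance = 1e-8)
    for (a in seq_len(min(3, length(p$singular_values)))) {
      expect_lt(min(max(abs(p$u1[, a] - sv$u[, a])),
                    max(abs(p$u1[, a] + sv$u[, a]))), 1e-8)
      sc <- cor((Xc %*% sv$u[, a]), (Yc %*% sv$v[, a]))
      expect_equal(abs(p$correlations[a]), abs(as.vector(sc)),
                   tolerance = 1e-8)
    }
    expect_equal(sum(p$pct_covariance_all), 100, tolerance = 1e-6)
    expect_true(all(abs(p$correlations) <= 1 + 1e-12))
  }
})

test_that("2B-PLS separates coupled and independent blocks", {
  set.seed(15)
  X <- matrix(stats::rnorm(200), 20)
  self <- two_block_pls(X, X)
  expect_equal(self$correlations[1], 1, tolerance = 1e-8)
  expect_equal(self$rv, 1, tolerance = 1e-10)

  # independent low-dimensional blocks at n=100: axis-1 correlation small
  hits <- 0
  for (rep in 1:40) {
    A <- matrix(stats::rnorm(100 * 2), 100)
    B <- matrix(stats::rnorm(100 * 2), 100)
    if (abs(two_block_pls(A, B)$correlations[1]) < 0.3) hits <- hits + 1
  }
  expect_gte(hits / 40, 0.9)
})

test_that("RV coefficient obeys its defining identities", {
  set.seed(16)
  X <- matrix(stats::rnorm(50), 10)
  expect_equal(rv_coefficient(X, X), 1, tolerance = 1e-12)
  O <- rand_rotation()
  Xr <- cbind(X[, 1:3] %*% O, X[, 4:5])
  expect_equal(rv_coefficient(X[, 1:3], X[, 1:3] %*% O), 1,
               tolerance = 1e-10)
  Y <- matrix(stats::rnorm(30), 10)
  expect_equal(rv_coefficient(X, Y), rv_coefficient(Y, X),
               tolerance = 1e-12)
  # direct trace-formula oracle on small matrices
  A <- matrix(stats::rnorm(15), 5)
  B <- matrix(stats::rnorm(15), 5)
  Ac <- scale(A, scale = FALSE); Bc <- scale(B, scale = FALSE)
  sxy <- t(Ac) %*% Bc; sxx <- t(Ac) %*% Ac; syy <- t(Bc) %*% Bc
  oracle <- sum(diag(sxy %*% t(sxy))) /
    sqrt(sum(diag(sxx %*% sxx)) * sum(diag(syy %*% syy)))
  expect_equal(rv_coefficient(A, B), oracle, tolerance = 1e-12)
  expect_gte(rv_coefficient(A, B), 0)
  expect_lte(rv_coefficient(A, B), 1)
  expect_error(rv_coefficient(matrix(1, 5, 2), A), "zero-variance")
})

test_that("permutation p-values are seeded, bounded and calibrated", {
  set.seed(17)
  X <- matrix(stats::rnorm(60), 12)
  Y <- X + matrix(stats::rnorm(60), 12) * 0.1
  p1 <- pls_permutation_test(X, Y, n_perm = 99, seed = 5)
  p2 <- pls_permutation_test(X, Y, n_perm = 99, seed = 5)
  expect_identical(p1, p2)
  expect_equal(min(p1$p_rv), 1 / 100)           # strongly coupled blocks
  expect_gte(min(p1$p_covariance), 1 / 100)     # add-one lower bound
  p3 <- pls_permutation_test(X, Y, n_perm = 1000, seed = 1)
  expect_equal(p3$p_rv, 1 / 1001, tolerance = 1e-12)
})

test_that("PLS extreme shapes are symmetric and sign-faithful", {
  # width covariation: block-1 and block-2 x-extent share one factor
  set.seed(18)
  base1 <- matrix(stats::rnorm(30), 10) * 4
  base2 <- matrix(stats::rnorm(36), 12) * 4
  cfg1 <- list(); cfg2 <- list()
  tvals <- stats::rnorm(30)
  for (i in 1:30) {
    s <- 1 + 0.2 * tvals[i]
    cfg1[[i]] <- base1 %*% diag(c(s, 1, 1)) +
      matrix(stats::rnorm(30), 10) * 0.02
    cfg2[[i]] <- base2 %*% diag(c(s, 1, 1)) +
      matrix(stats::rnorm(36), 12) * 0.02
  }
  X <- do.call(rbind, lapply(cfg1, function(p) as.vector(t(p))))
  Y <- do.call(rbind, lapply(cfg2, function(p) as.vector(t(p))))
  p <- two_block_pls(X, Y)
  expect_gt(abs(p$correlations[1]), 0.95)

  ex0 <- pls_extreme_shapes(p, 1, 0)
  expect_lt(max(abs(ex0$positive$shape1 -
                      matrix(p$center1, 10, 3, byrow = TRUE))), 1e-10)
  ex <- pls_extreme_shapes(p, 1, 1)
  mid1 <- (ex$positive$shape1 + ex$negative$shape1) / 2
  expect_lt(max(abs(mid1 - matrix(p$center1, 10, 3, byrow = TRUE))), 1e-10)

  # width difference signs agree across blocks (generator has one factor)
  w1 <- diff(range(ex$positive$shape1[, 1])) -
    diff(range(ex$negative$shape1[, 1]))
  w2 <- diff(range(ex$positive$shape2[, 1])) -
    diff(range(ex$negative$shape2[, 1]))
  expect_gt(w1 * w2, 0)
  expect_error(pls_extreme_shapes(p, 999), "out of range")
})
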
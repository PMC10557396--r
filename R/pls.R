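#' Two-block partial least squares of paired shape blocks
#'
#' Singular value decomposition of the between-block cross-covariance of
#' column-centered data. Axis pairs maximize squared covariance; per-axis
#' correlations are the correlations of paired scores; the percentage of
#' total squared covariance sums to 100 over all axes. Axis signs follow a
#' fixed convention (first non-zero block-1 loading positive) so extreme
#' shapes are reproducible.
#'
#' @param block1,block2 `n x p` / `n x q` matrices (rows = specimens), lists
#'   of configurations, or [gpa()] results (aligned coordinates are used).
#' @return object of class `cf_pls`: `u1`, `u2` (loading matrices),
#'   `scores1`, `scores2`, `singular_values`, `pct_covariance`,
#'   `correlations`, `rv` (all-dimension RV coefficient), `center1`,
#'   `center2`.
#' @export
two_block_pls <- function(block1, block2) {
  X <- block_matrix(block1)
  Y <- block_matrix(block2)
  n <- nrow(X)
  if (nrow(Y) != n) stop("blocks must contain the same specimens")
  if (n < 3) stop("2B-PLS needs at least 3 specimens")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  C <- crossprod(Xc, Yc) / (n - 1)
  sv <- svd(C)
  naxes <- sum(sv$d > max(sv$d[1], 1e-300) * 1e-12)
  naxes <- max(naxes, 1L)
  u1 <- sv$u[, seq_len(naxes), drop = FALSE]
  u2 <- sv$v[, seq_len(naxes), drop = FALSE]
  d <- sv$d[seq_len(naxes)]
  # sign convention: first non-zero loading of each block-1 axis positive
  for (a in seq_len(naxes)) {
    nz <- which(abs(u1[, a]) > 1e-12)[1]
    if (!is.na(nz) && u1[nz, a] < 0) {
      u1[, a] <- -u1[, a]
      u2[, a] <- -u2[, a]
    }
  }
  s1 <- Xc %*% u1
  s2 <- Yc %*% u2
  correlations <- vapply(seq_len(naxes), function(a) {
    if (stats::sd(s1[, a]) < 1e-300 || stats::sd(s2[, a]) < 1e-300) 0
    else stats::cor(s1[, a], s2[, a])
  }, 0)
  pct <- 100 * sv$d^2 / sum(sv$d^2)
  structure(list(u1 = u1, u2 = u2, scores1 = s1, scores2 = s2,
                 singular_values = d,
                 pct_covariance = pct[seq_len(naxes)],
                 pct_covariance_all = pct,
                 correlations = correlations,
                 rv = rv_coefficient(Xc, Yc),
                 center1 = cx, center2 = cy),
            class = "cf_pls")
}

block_matrix <- function(block) {
  if (inherits(block, "cf_gpa"))
    return(do.call(rbind, lapply(block$aligned, flatten_config)))
  if (is.list(block) && !is.data.frame(block))
    return(do.call(rbind, lapply(block, function(b)
      flatten_config(config_points(b)))))
  as.matrix(block)
}

#' RV coefficient between two multivariate blocks
#'
#' `RV = tr(S_XY S_YX) / sqrt(tr(S_XX^2) tr(S_YY^2))` on column-centered
#' data; a matrix generalization of squared correlation, in `[0, 1]`,
#' symmetric, and invariant to orthogonal rotation of either block.
#'
#' @param X,Y matrices with the same number of rows.
#' @return scalar in `[0, 1]`.
#' @export
rv_coefficient <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  sxx <- sum(crossprod(Xc)^2)
  syy <- sum(crossprod(Yc)^2)
  if (sxx < 1e-300 || syy < 1e-300)
    stop("RV undefined for a zero-variance block")
  sxy <- sum(crossprod(Xc, Yc)^2)
  sxy / sqrt(sxx * syy)
}

#' Permutation test for two-block PLS association
#'
#' Permutes the specimen rows of block 2 and recomputes the per-axis squared
#' covariances, per-axis score correlations and the RV coefficient.
#' P-values use the add-one estimator `(1 + #[perm >= obs]) / (1 + n_perm)`,
#' so the smallest attainable p is `1 / (n_perm + 1)`.
#'
#' @param block1,block2 as in [two_block_pls()].
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed; results are deterministic given the seed.
#' @param n_axes number of leading axes to test (default 3, capped at rank).
#' @return list: `p_covariance`, `p_correlation` (per axis), `p_rv`,
#'   `observed` (the observed statistics), `n_perm`.
#' @export
pls_permutation_test <- function(block1, block2, n_perm = 1000L, seed = 1L,
                                 n_axes = 3L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  X <- block_matrix(block1)
  Y <- block_matrix(block2)
  n <- nrow(X)
  obs <- two_block_pls(X, Y)
  n_axes <- min(n_axes, length(obs$singular_values))
  obs_cov <- obs$singular_values[seq_len(n_axes)]^2
  obs_cor <- abs(obs$correlations[seq_len(n_axes)])
  obs_rv <- obs$rv
  ge_cov <- integer(n_axes)
  ge_cor <- integer(n_axes)
  ge_rv <- 0L
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    p <- two_block_pls(X, Y[perm, , drop = FALSE])
    na <- min(n_axes, length(p$singular_values))
    pc <- p$singular_values[seq_len(na)]^2
    pr <- abs(p$correlations[seq_len(na)])
    ge_cov[seq_len(na)] <- ge_cov[seq_len(na)] + (pc >= obs_cov[seq_len(na)])
    ge_cor[seq_len(na)] <- ge_cor[seq_len(na)] + (pr >= obs_cor[seq_len(na)])
    ge_rv <- ge_rv + (p$rv >= obs_rv)
  }
  list(p_covariance = (1 + ge_cov) / (1 + n_perm),
       p_correlation = (1 + ge_cor) / (1 + n_perm),
       p_rv = (1 + ge_rv) / (1 + n_perm),
       observed = list(covariance = obs_cov, correlation = obs_cor,
                       rv = obs_rv),
       n_perm = as.integer(n_perm))
}

#' Shapes at the extremes of a PLS axis
#'
#' Reconstructs block-1 and block-2 configurations displaced from their mean
#' shapes along a PLS axis by `multiple` times the observed score range
#' (half-range on each side), symmetric about the mean. Optionally warps a
#' mean-shape mesh to each extreme by TPS so regional movement patterns can
#' be visualized.
#'
#' @param pls a [two_block_pls()] result.
#' @param axis axis index.
#' @param multiple displacement in units of the half score range.
#' @param mean_mesh1,mean_mesh2 optional [cf_mesh()]es whose vertices will be
#'   TPS-warped from the mean configuration to the extremes (requires the
#'   blocks to be 3D configurations).
#' @return list with `positive` and `negative`, each containing `shape1`,
#'   `shape2` (`k x 3`) and optionally `mesh1`, `mesh2`; plus
#'   `displacement1`, `displacement2` (point-wise PLS+ minus PLS- vectors).
#' @export
pls_extreme_shapes <- function(pls, axis = 1L, multiple = 1,
                               mean_mesh1 = NULL, mean_mesh2 = NULL) {
  if (axis < 1 || axis > length(pls$singular_values))
    stop("axis out of range")
  half1 <- diff(range(pls$scores1[, axis])) / 2
  half2 <- diff(range(pls$scores2[, axis])) / 2
  mk <- function(sign) {
    v1 <- pls$center1 + sign * multiple * half1 * pls$u1[, axis]
    v2 <- pls$center2 + sign * multiple * half2 * pls$u2[, axis]
    out <- list(shape1 = unflatten_config(v1), shape2 = unflatten_config(v2))
    if (!is.null(mean_mesh1)) {
      w <- tps_fit(unflatten_config(pls$center1), out$shape1)
      m <- mean_mesh1
      m$vertices <- tps_apply(w, mean_mesh1$vertices)
      out$mesh1 <- m
    }
    if (!is.null(mean_mesh2)) {
      w <- tps_fit(unflatten_config(pls$center2), out$shape2)
      m <- mean_mesh2
      m$vertices <- tps_apply(w, mean_mesh2$vertices)
      out$mesh2 <- m
    }
    out
  }
  pos <- mk(1); neg <- mk(-1)
  list(positive = pos, negative = neg,
       displacement1 = pos$shape1 - neg$shape1,
       displacement2 = pos$shape2 - neg$shape2)
}
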
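#' Fit a 3D thin-plate-spline warp
#'
#' Interpolating (or, with `regularization > 0`, smoothing) volumetric spline
#' with the 3D biharmonic kernel `U(r) = r`. With zero regularization the
#' warp maps every source control point exactly onto its target.
#'
#' @param source `k x 3` control points (k >= 4, non-coplanar).
#' @param target `k x 3` target points.
#' @param regularization non-negative smoothing weight added to the kernel
#'   diagonal.
#' @return object of class `cf_tps` with the affine part, non-affine weights
#'   and control points.
#' @export
tps_fit <- function(source, target, regularization = 0) {
  src <- config_points(source)
  dst <- config_points(target)
  k <- nrow(src)
  if (nrow(dst) != k) stop("source and target must have equal point counts")
  if (k < 4) stop("TPS needs at least 4 control points")
  if (regularization < 0) stop("regularization must be >= 0")
  K <- as.matrix(stats::dist(src, diag = TRUE, upper = TRUE))
  if (regularization > 0) K <- K + diag(regularization, k)
  P <- cbind(1, src)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(dst, matrix(0, 4, 3))
  sol <- tryCatch({
    s0 <- solve(L, rhs)
    s0 + solve(L, rhs - L %*% s0)  # one step of iterative refinement
  }, error = function(e)
    stop("singular TPS system (coplanar or duplicated control points): ",
         conditionMessage(e)))
  structure(list(control = src, weights = sol[1:k, , drop = FALSE],
                 affine = sol[(k + 1):(k + 4), , drop = FALSE],
                 regularization = regularization),
            class = "cf_tps")
}

#' Apply a fitted TPS warp to points
#'
#' @param warp a [tps_fit()] result.
#' @param points `m x 3` matrix.
#' @return warped `m x 3` matrix.
#' @export
tps_apply <- function(warp, points) {
  pts <- config_points(points)
  # exact per-control distances (the |p|^2 + |c|^2 - 2 p.c expansion loses
  # ~1e-8 of precision near control points, which breaks interpolation)
  k <- nrow(warp$control)
  U <- matrix(0, nrow(pts), k)
  for (j in seq_len(k))
    U[, j] <- sqrt((pts[, 1] - warp$control[j, 1])^2 +
                   (pts[, 2] - warp$control[j, 2])^2 +
                   (pts[, 3] - warp$control[j, 3])^2)
  cbind(1, pts) %*% warp$affine + U %*% warp$weights
}

#' Bending energy of a TPS warp
#'
#' Zero iff the warp is affine; non-negative otherwise.
#'
#' @param warp a [tps_fit()] result.
#' @return scalar bending energy.
#' @export
tps_bending_energy <- function(warp) {
  K <- as.matrix(stats::dist(warp$control, diag = TRUE, upper = TRUE))
  e <- sum(diag(t(warp$weights) %*% K %*% warp$weights))
  # the 3D kernel r yields a negative-definite form on the weight subspace;
  # report magnitude so affine maps give exactly 0
  abs(e)
}

#' Closed-form similarity alignment (Kabsch--Umeyama)
#'
#' Finds the rotation `R`, uniform scale `S > 0` and translation `t`
#' minimizing `sum_i || q_i - (S * R p_i + t) ||^2` from paired points.
#' A reflection guard flips the smallest singular axis if needed so that
#' `det(R) = +1`.
#'
#' @param P `m x 3` source points (m >= 3).
#' @param Q `m x 3` target points.
#' @param with_scaling estimate `S` (default) or fix `S = 1`.
#' @return object of class `cf_similarity`: list with `R`, `s`, `t` and the
#'   attained objective (sum of squared residuals).
#' @export
similarity_align <- function(P, Q, with_scaling = TRUE) {
  P <- config_points(P); Q <- config_points(Q)
  m <- nrow(P)
  if (nrow(Q) != m) stop("P and Q must have the same number of points")
  if (m < 3) stop("similarity alignment needs at least 3 points")
  mp <- colMeans(P); mq <- colMeans(Q)
  Pc <- sweep(P, 2, mp); Qc <- sweep(Q, 2, mq)
  varP <- sum(Pc^2) / m
  if (varP < 1e-24) stop("degenerate input: all source points coincide")
  H <- t(Pc) %*% Qc / m
  sv <- svd(H)
  d <- diag(3)
  if (det(sv$u %*% t(sv$v)) < 0) d[3, 3] <- -1
  R <- sv$v %*% d %*% t(sv$u)
  s <- if (with_scaling) sum(diag(d) * sv$d) / varP else 1
  t_vec <- mq - s * as.vector(R %*% mp)
  fitted <- s * P %*% t(R) + matrix(t_vec, m, 3, byrow = TRUE)
  obj <- sum((Q - fitted)^2)
  structure(list(R = R, s = s, t = t_vec, objective = obj),
            class = "cf_similarity")
}

#' Apply a similarity transform to points
#' @param tf a [similarity_align()] result.
#' @param points `m x 3` matrix.
#' @export
similarity_apply <- function(tf, points) {
  pts <- config_points(points)
  tf$s * pts %*% t(tf$R) + matrix(tf$t, nrow(pts), 3, byrow = TRUE)
}

#' Invert a similarity transform
#' @param tf a [similarity_align()] result.
#' @export
similarity_invert <- function(tf) {
  Ri <- t(tf$R)
  si <- 1 / tf$s
  structure(list(R = Ri, s = si, t = -si * as.vector(Ri %*% tf$t),
                 objective = NA_real_), class = "cf_similarity")
}
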
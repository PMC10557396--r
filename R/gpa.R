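#' Generalized Procrustes analysis
#'
#' Iterative superimposition of landmark configurations: translation to a
#' common centroid, optional scaling to unit centroid size, and optimal
#' rotation to the evolving mean, until the mean shape changes by less than
#' `tol`. With scaling on, the result is invariant to arbitrary similarity
#' transforms of any input; without scaling, to rigid motions only.
#'
#' @param configs list of `k x 3` configurations (or [cf_config()]s).
#' @param with_scaling scale configurations to unit centroid size.
#' @param tol convergence threshold on the mean-shape change.
#' @param max_iter iteration cap.
#' @return object of class `cf_gpa`: `aligned` (list of `k x 3`), `mean`
#'   (`k x 3`), `centroid_sizes`, `distances` (Procrustes distance of each
#'   aligned configuration to the mean), `with_scaling`.
#' @export
gpa <- function(configs, with_scaling = TRUE, tol = 1e-10, max_iter = 200L) {
  pts <- lapply(configs, config_points)
  n <- length(pts)
  if (n < 2) stop("GPA needs at least 2 configurations")
  k <- nrow(pts[[1]])
  if (any(vapply(pts, nrow, 0L) != k))
    stop("all configurations must have the same number of points")
  cs <- vapply(pts, centroid_size, 0)
  if (any(cs < 1e-12)) stop("degenerate zero-size configuration")
  centered <- lapply(pts, function(p) sweep(p, 2, colMeans(p)))
  if (with_scaling)
    centered <- Map(function(p, s) p / s, centered, cs)
  mean_shape <- centered[[1]]
  if (with_scaling) mean_shape <- mean_shape / centroid_size(mean_shape)
  aligned <- centered
  for (it in seq_len(max_iter)) {
    aligned <- lapply(centered, function(p) p %*% opa_rotation(p, mean_shape))
    new_mean <- Reduce(`+`, aligned) / n
    if (with_scaling) new_mean <- new_mean / centroid_size(new_mean)
    delta <- sqrt(sum((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol) break
  }
  mean_shape <- Reduce(`+`, aligned) / n
  dists <- vapply(aligned, function(p) sqrt(sum((p - mean_shape)^2)), 0)
  structure(list(aligned = aligned, mean = mean_shape, centroid_sizes = cs,
                 distances = dists, with_scaling = with_scaling),
            class = "cf_gpa")
}

# optimal rotation (Kabsch) aligning p onto q, both centered
opa_rotation <- function(p, q) {
  H <- t(p) %*% q
  sv <- svd(H)
  d <- diag(3)
  if (det(sv$u %*% t(sv$v)) < 0) d[3, 3] <- -1
  sv$u %*% d %*% t(sv$v)
}

#' Procrustes distance between two configurations
#'
#' Centers both configurations, optionally scales them to unit centroid
#' size, optimally rotates one onto the other and returns the root sum of
#' squared differences. Symmetric; zero iff the shapes are identical up to
#' the allowed transforms.
#'
#' @param a,b `k x 3` configurations.
#' @param with_scaling remove size as well as position and orientation.
#' @return non-negative scalar.
#' @export
procrustes_distance <- function(a, b, with_scaling = TRUE) {
  pa <- config_points(a); pb <- config_points(b)
  if (nrow(pa) != nrow(pb)) stop("configurations must have equal k")
  pa <- sweep(pa, 2, colMeans(pa))
  pb <- sweep(pb, 2, colMeans(pb))
  if (with_scaling) {
    pa <- pa / centroid_size(pa)
    pb <- pb / centroid_size(pb)
  }
  R <- opa_rotation(pa, pb)
  sqrt(sum((pa %*% R - pb)^2))
}

#' Principal component analysis of aligned shapes
#'
#' PCA of the Procrustes-aligned coordinates; the retained dimension `d` is
#' the smallest number of components whose cumulative variance proportion
#' reaches `cumulative_threshold`.
#'
#' @param aligned a [gpa()] result or a list of aligned `k x 3` configs.
#' @param cumulative_threshold in (0, 1].
#' @return object of class `cf_shapespace`: `mean` (`k x 3`), `basis`
#'   (`3k x r`, orthonormal columns), `eigenvalues`, `cumulative`,
#'   `scores` (`n x r`), `d`.
#' @export
pca_shapes <- function(aligned, cumulative_threshold = 0.95) {
  if (cumulative_threshold <= 0 || cumulative_threshold > 1)
    stop("cumulative_threshold must be in (0, 1]")
  configs <- if (inherits(aligned, "cf_gpa")) aligned$aligned else aligned
  n <- length(configs)
  if (n < 3) stop("shape PCA needs at least 3 specimens")
  X <- do.call(rbind, lapply(configs, flatten_config))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0)
  eig <- sv$d^2 / (n - 1)
  r <- sum(sv$d > max(sv$d[1], 1) * 1e-12)
  r <- max(r, 1L)
  basis <- sv$v[, seq_len(r), drop = FALSE]
  eig <- eig[seq_len(r)]
  scores <- Xc %*% basis
  cumv <- cumsum(eig) / sum(eig)
  d <- which(cumv >= cumulative_threshold - 1e-12)[1]
  structure(list(mean = unflatten_config(mu), basis = basis,
                 eigenvalues = eig, cumulative = cumv,
                 scores = scores, d = as.integer(d)),
            class = "cf_shapespace")
}

#' Project configurations into a shape space
#' @param space a [pca_shapes()] result.
#' @param config a `k x 3` configuration aligned consistently with the
#'   training data (use [align_to_mean()] first for raw configurations).
#' @param d number of scores to return (default the space's `d`).
#' @return numeric score vector.
#' @export
shape_scores <- function(space, config, d = space$d) {
  x <- flatten_config(config_points(config)) - flatten_config(space$mean)
  as.vector(x %*% space$basis[, seq_len(d), drop = FALSE])
}

#' Reconstruct a configuration from shape-space scores
#' @param space a [pca_shapes()] result.
#' @param scores numeric score vector (length <= number of basis columns).
#' @return `k x 3` configuration.
#' @export
shape_from_scores <- function(space, scores) {
  d <- length(scores)
  v <- flatten_config(space$mean) +
    as.vector(space$basis[, seq_len(d), drop = FALSE] %*% scores)
  unflatten_config(v)
}

#' Align a configuration onto a mean shape (partial OPA)
#'
#' Centers, optionally unit-scales, and rotates `config` onto `mean_shape`.
#' Used to bring new specimens into a trained shape space's frame.
#'
#' @param config `k x 3` configuration.
#' @param mean_shape `k x 3` reference (typically a GPA mean).
#' @param with_scaling scale to unit centroid size.
#' @return aligned `k x 3` configuration.
#' @export
align_to_mean <- function(config, mean_shape, with_scaling = TRUE) {
  p <- config_points(config)
  p <- sweep(p, 2, colMeans(p))
  if (with_scaling) p <- p / centroid_size(p)
  m <- config_points(mean_shape)
  m <- sweep(m, 2, colMeans(m))
  p %*% opa_rotation(p, m)
}
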
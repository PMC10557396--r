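#' Poisson-disk (blue-noise) sampling of a mesh surface
#'
#' Draws area-weighted random candidates on the surface and thins them
#' greedily to a minimum spacing, with the spacing radius found by bisection
#' so the accepted count lands within the requested tolerance of `n_target`.
#' Deterministic for a given seed: the candidate stream is fixed before the
#' bisection starts.
#'
#' @param mesh a [cf_mesh()] with positive surface area.
#' @param n_target desired number of samples.
#' @param seed integer RNG seed.
#' @param tolerance relative tolerance on the sample count (default 0.02).
#' @param oversample candidate multiplier (default 12).
#' @return A [cf_config()] of semilandmarks (0 named landmarks), with
#'   attributes `radius` (the spacing used) and `seed`.
#' @export
poisson_disk_sample <- function(mesh, n_target, seed = 1L, tolerance = 0.02,
                                oversample = 12) {
  if (n_target < 1) stop("n_target must be >= 1")
  A <- mesh_area(mesh)
  if (A <= 0) stop("mesh has zero surface area")
  n_cand <- max(200L, ceiling(oversample * n_target))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  cand <- sample_surface_points(mesh, n_cand)
  if (n_cand <= n_target) {
    warning("n_target exceeds achievable density; returning best effort")
    return(structure(cf_config(cand), radius = 0, seed = seed))
  }
  # hexagonal-packing estimate of the spacing that yields n_target points
  r0 <- sqrt(2 * A / (sqrt(3) * n_target))
  lo <- r0 / 8; hi <- r0 * 4
  count_at <- function(r) sum(cf_poisson_thin(cand, r))
  # ensure the bracket contains n_target
  while (count_at(hi) > n_target && hi < r0 * 64) hi <- hi * 2
  best_r <- NA_real_; best_keep <- NULL
  for (it in 1:40) {
    mid <- (lo + hi) / 2
    keep <- cf_poisson_thin(cand, mid)
    k <- sum(keep)
    if (abs(k - n_target) <= max(1, tolerance * n_target)) {
      best_r <- mid; best_keep <- keep
      break
    }
    if (k > n_target) lo <- mid else hi <- mid
  }
  if (is.null(best_keep)) {
    best_r <- lo
    best_keep <- cf_poisson_thin(cand, lo)
    if (abs(sum(best_keep) - n_target) > max(1, tolerance * n_target) * 2)
      warning("poisson_disk_sample: count ", sum(best_keep),
              " outside tolerance of n_target ", n_target)
  }
  structure(cf_config(cand[best_keep, , drop = FALSE]),
            radius = best_r, seed = seed)
}

# area-weighted uniform random points on the surface
sample_surface_points <- function(mesh, n) {
  areas <- row_norms(face_normals(mesh)) / 2
  fidx <- sample.int(nrow(mesh$faces), n, replace = TRUE, prob = areas)
  u <- stats::runif(n); v <- stats::runif(n)
  flip <- u + v > 1
  u[flip] <- 1 - u[flip]; v[flip] <- 1 - v[flip]
  f <- mesh$faces[fidx, , drop = FALSE]
  a <- mesh$vertices[f[, 1], , drop = FALSE]
  b <- mesh$vertices[f[, 2], , drop = FALSE]
  cc <- mesh$vertices[f[, 3], , drop = FALSE]
  a + u * (b - a) + v * (cc - a)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Reconstruct a triangle mesh from a point cloud
#'
#' Triangulates the points without moving them: every output vertex is an
#' input point. Near-planar clouds are triangulated by 2D Delaunay in the
#' best-fit plane; closed (star-shaped) clouds by central projection onto the
#' unit sphere followed by spherical (convex-hull) triangulation. Faces whose
#' longest edge exceeds the largest radius are discarded, which bounds face
#' span the way a pivoting-ball radius would.
#'
#' @param points `n x 3` point matrix (n >= 4 for closed clouds).
#' @param radii maximum-edge radii in mm; default `{1,2,4} x` median
#'   nearest-neighbour spacing.
#' @return A [cf_mesh()] over the input points.
#' @export
reconstruct_surface <- function(points, radii = NULL) {
  pts <- config_points(points)
  n <- nrow(pts)
  if (n < 4) stop("reconstruction needs at least 4 points")
  ctr <- colMeans(pts)
  cpts <- sweep(pts, 2, ctr)
  sv <- svd(cpts, nu = 0)
  if (sv$d[2] < 1e-9 * sv$d[1])
    stop("degenerate point cloud: points are collinear")
  if (is.null(radii)) {
    nn <- median_nn_spacing(pts)
    radii <- c(1, 2, 4) * nn
  }
  planar <- sv$d[3] < 1e-6 * sv$d[1]
  if (planar) {
    uv <- cpts %*% sv$v[, 1:2]
    faces <- cf_delaunay2d(uv)
  } else {
    dirs <- normalize_rows(cpts)
    faces <- cf_convex_hull_faces(dirs)
  }
  # drop faces with an edge longer than the largest radius
  rmax <- max(radii)
  e1 <- row_norms(pts[faces[, 1], , drop = FALSE] - pts[faces[, 2], , drop = FALSE])
  e2 <- row_norms(pts[faces[, 2], , drop = FALSE] - pts[faces[, 3], , drop = FALSE])
  e3 <- row_norms(pts[faces[, 3], , drop = FALSE] - pts[faces[, 1], , drop = FALSE])
  keep <- pmax(e1, e2, e3) <= rmax
  if (!any(keep))
    stop("reconstruction produced no faces within the given radii")
  cf_mesh(pts, faces[keep, , drop = FALSE])
}

median_nn_spacing <- function(pts) {
  n <- nrow(pts)
  # deterministic subsample (no RNG) so callers stay reproducible
  idx <- if (n > 1500) unique(round(seq(1, n, length.out = 1500))) else seq_len(n)
  sub <- pts[idx, , drop = FALSE]
  d <- as.matrix(stats::dist(sub))
  diag(d) <- Inf
  stats::median(apply(d, 1, min))
}
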
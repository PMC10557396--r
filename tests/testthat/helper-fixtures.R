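# shared fixtures, built in code at test time

rot_x <- function(a) matrix(c(1, 0, 0,
                              0, cos(a), -sin(a),
                              0, sin(a), cos(a)), 3, 3, byrow = TRUE)
rot_z <- function(a) matrix(c(cos(a), -sin(a), 0,
                              sin(a), cos(a), 0,
                              0, 0, 1), 3, 3, byrow = TRUE)

rand_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

sphere_mesh <- function(subdivisions = 3, radius = 1) {
  m <- icosphere(subdivisions)
  m$vertices <- m$vertices * radius
  m
}

unit_cube_obj <- function(path) {
  writeLines(c(
    "v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0",
    "v 0 0 1", "v 1 0 1", "v 1 1 1", "v 0 1 1",
    "f 1 3 2", "f 1 4 3", "f 5 6 7", "f 5 7 8",
    "f 1 2 6", "f 1 6 5", "f 2 3 7", "f 2 7 6",
    "f 3 4 8", "f 3 8 7", "f 4 1 5", "f 4 5 8"), path)
  path
}

# disk-topology planar patch (open boundary)
disk_mesh <- function(nr = 6, nt = 16) {
  pts <- rbind(c(0, 0, 0))
  for (r in seq_len(nr)) {
    th <- seq(0, 2 * pi, length.out = nt + 1)[-(nt + 1)]
    pts <- rbind(pts, cbind(r / nr * cos(th), r / nr * sin(th), 0))
  }
  reconstruct_surface(pts, radii = 1)
}

# cached small synthetic cohorts (one generation per test run)
.cohort_cache <- new.env(parent = emptyenv())
cached_cohort <- function(key, spec) {
  if (!exists(key, envir = .cohort_cache))
    assign(key, generate_cohort(spec), envir = .cohort_cache)
  get(key, envir = .cohort_cache)
}
std_cohort <- function() cached_cohort(
  "std", cohort_spec(n = 8, seed = 42, subdivisions = 3))

row_norms_t <- function(m) sqrt(rowSums(m * m))

face_normals_t <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], ] - v[f[, 1], ]
  e2 <- v[f[, 3], ] - v[f[, 1], ]
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

# simple flat-configuration population with q latent factors
factor_configs <- function(n, k = 12, q = 3, sds = c(3, 2, 1), noise = 0,
                           seed = 1) {
  set.seed(seed)
  base <- matrix(stats::rnorm(k * 3), k, 3) * 5
  modes <- lapply(seq_len(q), function(j) matrix(stats::rnorm(k * 3), k, 3))
  lapply(seq_len(n), function(i) {
    z <- stats::rnorm(q) * sds[seq_len(q)]
    p <- base
    for (j in seq_len(q)) p <- p + z[j] * modes[[j]]
    p + matrix(stats::rnorm(k * 3), k, 3) * noise
  })
}
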
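#' Project points onto the nearest point of a target surface
#'
#' Exact point-to-triangle projection (face interior, edge or vertex), ties
#' broken by lowest face index; point order is preserved.
#'
#' @param points `m x 3` matrix (e.g. deformed-template semilandmarks).
#' @param target a [cf_mesh()] with faces.
#' @return A [cf_config()] of projected points with attribute `distance`
#'   (the pre-projection distances).
#' @export
project_semilandmarks <- function(points, target) {
  if (is.null(target$faces) || nrow(target$faces) == 0)
    stop("target mesh has no faces")
  pts <- config_points(points)
  res <- cf_closest_points_mesh(pts, target$vertices, target$faces)
  out <- cf_config(res[, 1:3, drop = FALSE],
                   n_landmarks = if (inherits(points, "cf_config"))
                     points$n_landmarks else 0L)
  attr(out, "distance") <- res[, 4]
  attr(out, "face") <- as.integer(res[, 5])
  out
}

mean_surface_distance <- function(points, target) {
  res <- cf_closest_points_mesh(config_points(points), target$vertices,
                                target$faces)
  mean(res[, 4])
}

#' Non-rigid ICP registration of a template mesh onto a target
#'
#' Optimal-step non-rigid ICP with per-vertex affine transforms regularized
#' by an edge-difference stiffness term, run over a decreasing stiffness
#' schedule. Landmark pairs enter as weighted soft constraints whose weight
#' decays to 1 in the final stage. Correspondences are pruned when their
#' distance exceeds 4x the median or their normals disagree by more than 60
#' degrees. Fully deterministic.
#'
#' @param template a [cf_mesh()] (deformed copy is returned).
#' @param target a [cf_mesh()].
#' @param landmark_pairs optional list with `src_idx` (template vertex
#'   indices) and `dst` (`L x 3` target positions).
#' @param stiffness_schedule decreasing stiffness values (one stage each).
#' @param max_iter maximum iterations per stage.
#' @param landmark_weight initial soft-constraint weight.
#' @param tol per-stage convergence threshold on the mean vertex update (mm).
#' @param residual_target registration is flagged unconverged if the final
#'   mean closest-point residual exceeds this (mm).
#' @return object of class `cf_nicp`: `mesh` (deformed template),
#'   `residuals` (per-iteration mean source-to-target distance), `stages`
#'   (stage index per iteration), `schedule`, `converged`.
#' @export
nicp_register <- function(template, target, landmark_pairs = NULL,
                          stiffness_schedule = c(50, 20, 10, 5, 2),
                          max_iter = 10L, landmark_weight = 10,
                          tol = 1e-3, residual_target = 0.5) {
  if (nrow(template$vertices) == 0 || nrow(target$vertices) == 0)
    stop("empty mesh")
  if (is.null(template$normals)) template <- compute_vertex_normals(template)
  if (is.null(target$normals)) target <- compute_vertex_normals(target)
  n <- nrow(template$vertices)
  V0 <- template$vertices
  # unique undirected edges
  f <- template$faces
  eall <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  eall <- t(apply(eall, 1, sort))
  edges <- unique(eall)
  ne <- nrow(edges)
  gamma <- 1
  # stiffness matrix M (x) G : 4 rows per edge
  i_mg <- rep(seq_len(4 * ne), 2)
  j_mg <- c(as.vector(vapply(1:4, function(k) 4L * (edges[, 1] - 1L) + k,
                             integer(ne))),
            as.vector(vapply(1:4, function(k) 4L * (edges[, 2] - 1L) + k,
                             integer(ne))))
  # careful: build row indices matching column layout above
  rows_blk <- as.vector(vapply(1:4, function(k) 4L * (seq_len(ne) - 1L) + k,
                               integer(ne)))
  i_mg <- c(rows_blk, rows_blk)
  x_mg <- c(rep(c(-1, -1, -1, -gamma), each = ne),
            rep(c(1, 1, 1, gamma), each = ne))
  MG <- Matrix::sparseMatrix(i = i_mg, j = j_mg, x = x_mg,
                             dims = c(4 * ne, 4 * n))
  # data matrix D: row i has [v_i, 1] in block i
  make_D <- function(V, idx = seq_len(n)) {
    m <- length(idx)
    Matrix::sparseMatrix(
      i = rep(seq_len(m), 4),
      j = c(4L * (idx - 1L) + 1L, 4L * (idx - 1L) + 2L,
            4L * (idx - 1L) + 3L, 4L * (idx - 1L) + 4L),
      x = c(V[idx, 1], V[idx, 2], V[idx, 3], rep(1, m)),
      dims = c(m, 4 * n))
  }
  D <- make_D(V0)
  has_lm <- !is.null(landmark_pairs) && length(landmark_pairs$src_idx) > 0
  if (has_lm) {
    DL <- make_D(V0, as.integer(landmark_pairs$src_idx))
    UL <- as_pts(landmark_pairs$dst)
  }
  ef <- target$faces
  med_edge <- stats::median(row_norms(
    target$vertices[ef[, 1], , drop = FALSE] -
      target$vertices[ef[, 2], , drop = FALSE]))
  # X starts as stacked identity transforms
  X <- do.call(rbind, rep(list(rbind(diag(3), c(0, 0, 0))), n))
  residuals <- numeric(0)
  stages <- integer(0)
  nstage <- length(stiffness_schedule)
  for (si in seq_len(nstage)) {
    alpha <- stiffness_schedule[si]
    beta <- if (nstage == 1) 1 else
      landmark_weight + (1 - landmark_weight) * (si - 1) / (nstage - 1)
    for (it in seq_len(max_iter)) {
      Vd <- as.matrix(D %*% X)
      cp <- cf_closest_points_mesh(Vd, target$vertices, target$faces)
      dists <- cp[, 4]
      w <- rep(1, n)
      # prune outlier correspondences; the absolute floor (median target
      # edge length) keeps near-converged solutions from pruning everything
      thr <- max(4 * stats::median(dists), med_edge)
      w[dists > thr] <- 0
      # normal compatibility
      fidx <- as.integer(cp[, 5])
      tn <- normalize_rows(face_normals(target))[fidx, , drop = FALSE]
      sn <- deformed_normals(V0, Vd, template$faces)
      cosang <- rowSums(tn * sn)
      w[cosang < cos(60 * pi / 180)] <- 0
      if (all(w == 0)) w <- rep(1, n)
      U <- cp[, 1:3, drop = FALSE]
      WD <- Matrix::Diagonal(x = w) %*% D
      A <- rbind(alpha * MG, WD)
      B <- rbind(Matrix::Matrix(0, 4 * ne, 3), w * U)
      if (has_lm) {
        A <- rbind(A, beta * DL)
        B <- rbind(B, beta * UL)
      }
      AtA <- Matrix::crossprod(A)
      AtB <- Matrix::crossprod(A, B)
      Xnew <- as.matrix(Matrix::solve(AtA, AtB))
      upd <- sqrt(mean((Xnew - X)^2))
      X <- Xnew
      # pre-update residual (one closest-point pass per iteration); the
      # post-update residual of the last iterate is appended after the loop
      residuals <- c(residuals, mean(dists))
      stages <- c(stages, si)
      if (upd < tol) break
    }
  }
  out_mesh <- template
  out_mesh$vertices <- as.matrix(D %*% X)
  out_mesh$normals <- NULL
  final_res <- mean(cf_closest_points_mesh(out_mesh$vertices,
                                           target$vertices,
                                           target$faces)[, 4])
  residuals <- c(residuals, final_res)
  stages <- c(stages, length(stiffness_schedule))
  structure(list(mesh = out_mesh, residuals = residuals, stages = stages,
                 schedule = stiffness_schedule,
                 converged = final_res <= residual_target,
                 X = X), class = "cf_nicp")
}

# approximate normals of the deformed template for correspondence pruning
deformed_normals <- function(V0, Vd, faces) {
  m <- cf_mesh(Vd, faces)
  fn <- face_normals(m)
  nv <- nrow(Vd)
  acc <- matrix(0, nv, 3)
  for (k in 1:3) {
    idx <- faces[, k]
    acc[, 1] <- acc[, 1] + tapply_add(fn[, 1], idx, nv)
    acc[, 2] <- acc[, 2] + tapply_add(fn[, 2], idx, nv)
    acc[, 3] <- acc[, 3] + tapply_add(fn[, 3], idx, nv)
  }
  normalize_rows(acc)
}

#' Hybrid TPS + NICP template-to-target registration
#'
#' Stage 1 warps the template by a thin-plate spline interpolating the
#' landmark pairs; stage 2 refines by non-rigid ICP initialized from the TPS
#' result. The stage-2 residual never exceeds the stage-1 residual (NICP is
#' accepted only if it improves the mean closest-point distance).
#'
#' @inheritParams nicp_register
#' @param ... passed to [nicp_register()].
#' @return list: `mesh` (deformed template), `tps_residual`,
#'   `nicp_residual`, `warp` (the TPS), `nicp` (stage-2 detail).
#' @export
hybrid_register <- function(template, target, landmark_pairs, ...) {
  if (length(landmark_pairs$src_idx) != nrow(as_pts(landmark_pairs$dst)))
    stop("mismatched landmark counts")
  src_pts <- template$vertices[landmark_pairs$src_idx, , drop = FALSE]
  warp <- tps_fit(src_pts, landmark_pairs$dst)
  warped <- template
  warped$vertices <- tps_apply(warp, template$vertices)
  warped$normals <- NULL
  tps_res <- mean_surface_distance(warped$vertices, target)
  nicp <- nicp_register(warped, target, landmark_pairs = landmark_pairs, ...)
  nicp_res <- mean_surface_distance(nicp$mesh$vertices, target)
  if (nicp_res <= tps_res) {
    mesh <- nicp$mesh
  } else {
    mesh <- warped
    nicp_res <- tps_res
  }
  list(mesh = mesh, tps_residual = tps_res, nicp_residual = nicp_res,
       warp = warp, nicp = nicp)
}
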
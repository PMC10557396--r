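#' Laplacian mesh deformation with anchor constraints
#'
#' Deforms a mesh so that its differential (Laplacian) coordinates stay as
#' close as possible to the input's while a set of anchor vertices is pulled
#' to prescribed positions:
#' `E = sum_i || delta(g_i) - delta(v_i) ||^2 + w^2 sum_j || l_j - g_j ||^2`,
#' solved as one sparse least-squares system per coordinate. The anchor
#' residual decreases monotonically as `w` grows; `w = 1000` effectively
#' makes the anchors fixed constants.
#'
#' @param mesh a connected [cf_mesh()] (vertices `v_i`).
#' @param anchor_idx integer vertex indices `j`.
#' @param anchor_pts `length(anchor_idx) x 3` target positions `l_j`.
#' @param weight anchor weight `w` (default 1).
#' @param laplacian `"uniform"` (graph, default) or `"cotangent"`.
#' @return object of class `cf_refined`: `mesh` (same topology, new vertex
#'   positions), `anchor_residual` (max over anchors, mm), `weight`.
#' @export
laplacian_refine <- function(mesh, anchor_idx, anchor_pts, weight = 1,
                             laplacian = c("uniform", "cotangent")) {
  laplacian <- match.arg(laplacian)
  anchor_idx <- as.integer(anchor_idx)
  anchor_pts <- as_pts(anchor_pts)
  n <- nrow(mesh$vertices)
  if (length(anchor_idx) == 0) stop("at least one anchor required")
  if (any(anchor_idx < 1 | anchor_idx > n)) stop("anchor index out of range")
  L <- mesh_laplacian(mesh, laplacian)
  comp <- mesh_components(mesh)
  if (length(setdiff(unique(comp), unique(comp[anchor_idx]))) > 0)
    stop("underdetermined: a connected component has no anchor")
  delta <- L %*% mesh$vertices
  m <- length(anchor_idx)
  S <- Matrix::sparseMatrix(i = seq_len(m), j = anchor_idx, x = rep(1, m),
                            dims = c(m, n))
  A <- rbind(L, weight * S)
  B <- rbind(delta, weight * anchor_pts)
  AtA <- Matrix::crossprod(A)
  G <- as.matrix(Matrix::solve(AtA, Matrix::crossprod(A, B)))
  out <- mesh
  out$vertices <- G
  out$normals <- NULL
  res <- row_norms(G[anchor_idx, , drop = FALSE] - anchor_pts)
  structure(list(mesh = out, anchor_residual = max(res), weight = weight),
            class = "cf_refined")
}

# row-normalized graph Laplacian L = I - D^-1 A (uniform) or cotangent
mesh_laplacian <- function(mesh, type = "uniform") {
  n <- nrow(mesh$vertices)
  f <- mesh$faces
  if (type == "uniform") {
    e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
    e <- rbind(e, e[, 2:1])
    e <- unique(e)
    A <- Matrix::sparseMatrix(i = e[, 1], j = e[, 2], x = rep(1, nrow(e)),
                              dims = c(n, n))
  } else {
    v <- mesh$vertices
    cot_at <- function(a, b, c) {
      # cotangent of the angle at a in triangle (a, b, c)
      u <- v[b, , drop = FALSE] - v[a, , drop = FALSE]
      w <- v[c, , drop = FALSE] - v[a, , drop = FALSE]
      num <- rowSums(u * w)
      den <- row_norms(cross_rows(u, w))
      num / pmax(den, 1e-12)
    }
    i <- c(f[, 2], f[, 3], f[, 1], f[, 3], f[, 1], f[, 2])
    j <- c(f[, 3], f[, 2], f[, 3], f[, 1], f[, 2], f[, 1])
    w3 <- cbind(cot_at(f[, 1], f[, 2], f[, 3]),
                cot_at(f[, 2], f[, 3], f[, 1]),
                cot_at(f[, 3], f[, 1], f[, 2]))
    x <- 0.5 * c(w3[, 1], w3[, 1], w3[, 2], w3[, 2], w3[, 3], w3[, 3])
    A <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
  }
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  Matrix::Diagonal(n) - Matrix::Diagonal(x = 1 / deg) %*% A
}

mesh_components <- function(mesh) {
  n <- nrow(mesh$vertices)
  f <- mesh$faces
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (r in seq_len(nrow(f))) {
    a <- find(f[r, 1]); b <- find(f[r, 2]); c <- find(f[r, 3])
    parent[b] <- a; parent[find(c)] <- find(a)
  }
  vapply(seq_len(n), find, 0L)
}
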
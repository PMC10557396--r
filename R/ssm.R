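#' Build a facial statistical shape model
#'
#' GPA (with unit-size scaling) followed by PCA of the aligned face
#' configurations. The model holds the mean face, orthonormal deformation
#' modes, eigenvalues, and the dimension `d` reaching the cumulative
#' variance threshold. Any training face is represented exactly at full
#' rank.
#'
#' @param face_configs list of >= 3 `k x 3` face configurations in fixed
#'   correspondence.
#' @param cumulative_threshold variance proportion retained.
#' @return object of class `cf_ssm`: `mean` (`k x 3`), `basis` (`3k x r`),
#'   `eigenvalues`, `d`, `scores` (training scores), `gpa_mean_size`.
#' @export
build_ssm <- function(face_configs, cumulative_threshold = 0.95) {
  if (length(face_configs) < 3) stop("SSM needs at least 3 faces")
  g <- gpa(face_configs, with_scaling = TRUE)
  total_var <- sum(vapply(g$aligned, function(a) sum((a - g$mean)^2), 0))
  if (total_var < 1e-18) {
    # identical faces: the model is just the mean, with no modes
    return(structure(list(mean = g$mean,
                          basis = matrix(0, 3 * nrow(g$mean), 0),
                          eigenvalues = numeric(0), d = 0L,
                          scores = matrix(0, length(face_configs), 0)),
                     class = "cf_ssm"))
  }
  sp <- pca_shapes(g, cumulative_threshold)
  structure(list(mean = sp$mean, basis = sp$basis,
                 eigenvalues = sp$eigenvalues, d = sp$d,
                 scores = sp$scores, cumulative = sp$cumulative),
            class = "cf_ssm")
}

#' @export
print.cf_ssm <- function(x, ...) {
  cat(sprintf("<cf_ssm> %d points, %d modes (d = %d at threshold)\n",
              nrow(x$mean), ncol(x$basis), x$d))
  invisible(x)
}

#' Reconstruct a face from SSM coefficients
#' @param ssm a [build_ssm()] result.
#' @param beta coefficient vector (length <= number of modes; padded with 0).
#' @return `k x 3` face configuration.
#' @export
ssm_face <- function(ssm, beta) {
  r <- ncol(ssm$basis)
  b <- rep(0, r)
  b[seq_along(beta)] <- beta
  v <- flatten_config(ssm$mean)
  if (r > 0) v <- v + as.vector(ssm$basis %*% b)
  unflatten_config(v)
}

#' Fit SSM coefficients to partial correspondences
#'
#' Closed-form ridge solution of
#' `argmin_beta || U_s beta - (tp - mean) ||^2 + lambda^2 ||beta||^2`,
#' restricted to the corresponded rows, then reconstruction over all points,
#' which fills in geometry (eyes, ears, regions missing from the coarse
#' face).
#'
#' @param ssm a [build_ssm()] result.
#' @param idx integer vector of SSM point indices with correspondences.
#' @param pts `length(idx) x 3` target positions in the SSM frame.
#' @param lambda ridge weight; default `1e-3 *` the leading eigenvalue.
#' @param d number of modes used (default the model's `d`).
#' @return list: `beta`, `face` (`k x 3` fitted configuration `Q(beta)`),
#'   `objective`.
#' @export
fit_ssm <- function(ssm, idx, pts, lambda = NULL, d = ssm$d) {
  if (length(idx) == 0) stop("empty correspondence set")
  pts <- as_pts(pts)
  if (nrow(pts) != length(idx)) stop("one target point per index required")
  if (is.null(lambda))
    lambda <- if (length(ssm$eigenvalues) > 0) 1e-3 * ssm$eigenvalues[1] else 0
  d <- min(d, ncol(ssm$basis))
  if (d == 0)
    return(list(beta = numeric(0), face = ssm$mean, objective = 0))
  rows <- as.vector(rbind(3 * (idx - 1) + 1, 3 * (idx - 1) + 2,
                          3 * (idx - 1) + 3))
  Us <- ssm$basis[rows, seq_len(d), drop = FALSE]
  target <- as.vector(t(pts)) - flatten_config(ssm$mean)[rows]
  A <- crossprod(Us) + diag(lambda^2, d)
  beta <- as.vector(solve(A, crossprod(Us, target)))
  resid <- as.vector(Us %*% beta) - target
  list(beta = beta, face = ssm_face(ssm, beta),
       objective = sum(resid^2) + lambda^2 * sum(beta^2))
}
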
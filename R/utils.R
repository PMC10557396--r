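# internal helpers shared across modules

row_norms <- function(m) sqrt(rowSums(m * m))

normalize_rows <- function(m) {
  n <- row_norms(m)
  n[n == 0] <- 1
  m / n
}

cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_pts <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3) stop("expected an n x 3 point matrix", call. = FALSE)
  dimnames(x) <- NULL
  x
}

centroid_size <- function(pts) {
  ctr <- colMeans(pts)
  sqrt(sum(sweep(pts, 2, ctr)^2))
}

# flatten k x 3 configurations to row vectors (x1 y1 z1 x2 y2 z2 ...)
flatten_config <- function(pts) as.vector(t(pts))
unflatten_config <- function(v) matrix(v, ncol = 3, byrow = TRUE)
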
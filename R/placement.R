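# Component placement onto the approximated envelope and the transform into
# the SSM frame.

# resample a closed polyline (matrix of loop vertices, implicitly closed) to
# m points equally spaced in normalized arc length
resample_loop <- function(pts, m = 100L) {
  pts <- as_pts(pts)
  k <- nrow(pts)
  closed <- rbind(pts, pts[1, ])
  seg <- row_norms(diff(closed))
  cum <- c(0, cumsum(seg))
  total <- cum[k + 1]
  if (total <= 0) stop("degenerate boundary loop")
  s <- seq(0, total, length.out = m + 1)[seq_len(m)]
  out <- matrix(0, m, 3)
  j <- 1
  for (i in seq_len(m)) {
    while (cum[j + 1] < s[i]) j <- j + 1
    t <- if (seg[j] > 0) (s[i] - cum[j]) / seg[j] else 0
    out[i, ] <- (1 - t) * closed[j, ] + t * closed[j + 1, ]
  }
  out
}

# best similarity transform mapping loop P onto loop Q over all cyclic
# offsets and both directions; both m x 3, already resampled
align_loops <- function(P, Q) {
  m <- nrow(P)
  best <- NULL
  best_rms <- Inf
  for (rev in c(FALSE, TRUE)) {
    Pr <- if (rev) P[m:1, , drop = FALSE] else P
    for (off in 0:(m - 1)) {
      idx <- ((seq_len(m) - 1 + off) %% m) + 1
      tf <- similarity_align(Pr[idx, , drop = FALSE], Q)
      rms <- sqrt(tf$objective / m)
      if (rms < best_rms) {
        best_rms <- rms
        best <- tf
      }
    }
  }
  list(transform = best, rms = best_rms)
}

#' Place an approximated component onto the facial envelope
#'
#' Aligns a predicted nose/mouth shape to the envelope's matching boundary
#' curve: both boundary loops are resampled to `m` points by normalized arc
#' length, the cyclic offset and direction minimizing the post-alignment RMS
#' are found exhaustively, and the closed-form similarity transform
#' (rotation, translation, uniform scale) is applied to the whole component.
#'
#' @param component list with `points` (`k x 3` component configuration) and
#'   `faces` (its triangulation), e.g. a predicted organ shape on the face
#'   template's component submesh.
#' @param envelope a [cf_mesh()] whose boundary exposes the component's rim
#'   (typically the deformed average facial envelope).
#' @param envelope_labels optional [cf_labels()] over the envelope vertices.
#' @param component_id label of the rim to use when `envelope_labels` is
#'   given; otherwise the envelope's boundary loop nearest in size is used.
#' @param m number of resampled boundary correspondences (>= 3).
#' @param prescale initial scale: `"loop"` matches the component's boundary
#'   centroid size to the target loop before alignment (the similarity fit
#'   then refines it); `"none"` skips it.
#' @return list: `points` (placed component points), `mesh`, `transform`
#'   (the [similarity_align()] result), `boundary_rms` (post-placement),
#'   `initial_rms`.
#' @export
place_component <- function(component, envelope, envelope_labels = NULL,
                            component_id = NULL, m = 100L,
                            prescale = c("loop", "none")) {
  prescale <- match.arg(prescale)
  if (m < 3) stop("need at least 3 boundary correspondences")
  cpts <- config_points(component$points)
  cmesh <- cf_mesh(cpts, component$faces)
  closs <- extract_boundary_loops(cmesh)
  if (length(closs) == 0) stop("component has no boundary loop")
  cloop <- closs[[which.max(lengths(closs))]]
  if (!is.null(envelope_labels)) {
    eloops <- extract_boundary_loops(envelope, envelope_labels, component_id)
  } else {
    eloops <- extract_boundary_loops(envelope)
  }
  if (length(eloops) == 0) stop("envelope exposes no boundary loop")
  # pick the envelope loop whose arc length is closest to the component's
  loop_len <- function(mesh, loop) {
    p <- mesh$vertices[loop, , drop = FALSE]
    sum(row_norms(diff(rbind(p, p[1, ]))))
  }
  clen <- loop_len(cmesh, cloop)
  if (length(eloops) > 1 && is.null(envelope_labels)) {
    lens <- vapply(eloops, function(l) loop_len(envelope, l), 0)
    eloop <- eloops[[which.min(abs(lens - clen))]]
  } else eloop <- eloops[[which.max(lengths(eloops))]]
  Q <- resample_loop(envelope$vertices[eloop, , drop = FALSE], m)
  src <- cpts
  if (prescale == "loop") {
    # match boundary centroid size and centroid as an initial metric guess
    p0 <- cpts[cloop, , drop = FALSE]
    s0 <- centroid_size(Q) / centroid_size(p0)
    src <- sweep(sweep(cpts, 2, colMeans(p0)) * s0, 2, colMeans(Q), `+`)
  }
  P <- resample_loop(src[cloop, , drop = FALSE], m)
  initial_rms <- sqrt(mean(rowSums((P - Q)^2)))
  al <- align_loops(P, Q)
  placed <- similarity_apply(al$transform, src)
  list(points = placed, mesh = cf_mesh(placed, component$faces),
       transform = al$transform, boundary_rms = al$rms,
       initial_rms = initial_rms)
}

#' Transform the coarse face into the SSM frame
#'
#' Establishes correspondences by casting each skull envelope point's fixed
#' ray at the deformed average face: the nearest SSM point index of the hit
#' pairs the coarse envelope point `tp_i` (which lies on the same ray by
#' construction) with a mean-face index. A similarity transform into the SSM
#' frame is then estimated from these pairs.
#'
#' @param skull_points `k x 3` dry-skull envelope points (ray origins).
#' @param directions `k x 3` fixed measurement directions.
#' @param envelope_points `k x 3` coarse envelope points (`tp_i`, on the rays).
#' @param deformed_avg_face a [cf_mesh()] of the average face warped to the
#'   dry skull.
#' @param ssm_points `n x 3` SSM point positions indexed like the face
#'   configuration (the deformed average face's vertices map to these).
#' @param max_depth ray length limit (mm).
#' @return list: `idx` (SSM indices), `pts` (matched coarse points),
#'   `transform` (similarity into the SSM frame), `n_dropped`.
#' @export
transform_to_ssm_frame <- function(skull_points, directions, envelope_points,
                                   deformed_avg_face, ssm_points,
                                   max_depth = 120) {
  s <- as_pts(skull_points)
  dirs <- normalize_rows(as_pts(directions))
  tp <- as_pts(envelope_points)
  t_hit <- cf_ray_mesh_first_hit(s, dirs, deformed_avg_face$vertices,
                                 deformed_avg_face$faces, max_depth, 0)
  ok <- which(!is.na(t_hit))
  if (length(ok) < 3) stop("fewer than 3 valid ray correspondences")
  hits <- s[ok, , drop = FALSE] + dirs[ok, , drop = FALSE] * t_hit[ok]
  # nearest deformed-average-face vertex gives the SSM point index
  idx <- integer(length(ok))
  fv <- deformed_avg_face$vertices
  for (i in seq_along(ok)) {
    d2 <- rowSums(sweep(fv, 2, hits[i, ])^2)
    idx[i] <- which.min(d2)
  }
  tf <- similarity_align(tp[ok, , drop = FALSE],
                         as_pts(ssm_points)[idx, , drop = FALSE])
  list(idx = idx, pts = tp[ok, , drop = FALSE], transform = tf,
       n_dropped = nrow(s) - length(ok), ray_ok = ok)
}
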
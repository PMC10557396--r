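#' Measure facial soft-tissue depths along fixed directions
#'
#' For each skull landmark/semilandmark `s_i`, casts a ray along its fixed
#' measurement direction `n_i` (taken from the cohort-average skull and held
#' constant across specimens) and records the Euclidean distance `d_i` to the
#' first intersection with the facial surface. Rays that miss within
#' `max_depth` yield missing depths.
#'
#' @param skull_config `k x 3` skull points (mm).
#' @param directions `k x 3` unit measurement directions.
#' @param face a [cf_mesh()] of the facial surface.
#' @param max_depth maximum depth to search (mm, default 60).
#' @return object of class `cf_fstd`: `skull` points, `directions`, `depths`
#'   (NA where the ray missed), and `face_points` (`s_i + d_i n_i`).
#' @export
measure_fstd <- function(skull_config, directions, face, max_depth = 60) {
  s <- config_points(skull_config)
  n <- as_pts(directions)
  if (nrow(n) != nrow(s)) stop("one direction per skull point required")
  if (is.null(face$faces) || nrow(face$faces) == 0)
    stop("empty face mesh")
  n <- normalize_rows(n)
  d <- cf_ray_mesh_first_hit(s, n, face$vertices, face$faces,
                             max_depth, 0)
  fp <- s + n * ifelse(is.na(d), 0, d)
  fp[is.na(d), ] <- NA_real_
  structure(list(skull = s, directions = n, depths = as.numeric(d),
                 face_points = fp), class = "cf_fstd")
}

#' Descriptive statistics of FSTD fields across a cohort
#'
#' Per-point mean and sample standard deviation (ddof = 1) over available
#' depths, plus a cohort-wide summary over every point-specimen depth.
#' Missing depths are excluded, with availability counts reported; points
#' missing in all specimens are flagged.
#'
#' @param fields list of [measure_fstd()] results with aligned point orders.
#' @return object of class `cf_fstd_stats`: `mean` and `sd` (per point,
#'   mm), `n_available`, `cohort_mean`, `cohort_sd`, `all_missing` (indices).
#' @export
fstd_statistics <- function(fields) {
  if (length(fields) < 1) stop("need at least one FSTD field")
  k <- length(fields[[1]]$depths)
  if (any(vapply(fields, function(f) length(f$depths), 0L) != k))
    stop("FSTD fields have mismatched point counts")
  D <- do.call(rbind, lapply(fields, `[[`, "depths"))  # n x k
  n_avail <- colSums(!is.na(D))
  mu <- colMeans(D, na.rm = TRUE)
  sdv <- apply(D, 2, stats::sd, na.rm = TRUE)
  sdv[n_avail <= 1] <- 0
  all_missing <- which(n_avail == 0)
  mu[all_missing] <- NA_real_
  vals <- D[!is.na(D)]
  structure(list(mean = mu, sd = sdv, n_available = n_avail,
                 cohort_mean = mean(vals), cohort_sd = stats::sd(vals),
                 all_missing = all_missing,
                 directions = fields[[1]]$directions),
            class = "cf_fstd_stats")
}

#' Build an approximated facial envelope from a dry skull
#'
#' Offsets every skull point along its fixed measurement direction by the
#' cohort-mean depth, `h_i = s_i + n_i d_i`, and triangulates the resulting
#' points. Points with a missing mean depth are imputed by
#' inverse-distance-weighted averaging over the 8 nearest measured skull
#' points.
#'
#' @param skull_config `k x 3` dry-skull points.
#' @param directions `k x 3` unit directions (from the average skull).
#' @param mean_depths length-`k` mean depths (mm; NA allowed).
#' @param faces optional precomputed triangulation (`m x 3` indices over the
#'   k points); when NULL the surface is reconstructed from scratch.
#' @param radii passed to [reconstruct_surface()] when `faces` is NULL.
#' @return list: `points` ([cf_config()] of envelope points), `mesh`
#'   ([cf_mesh()]), `depths` (imputed depth vector), `imputed` (indices).
#' @export
build_envelope <- function(skull_config, directions, mean_depths,
                           faces = NULL, radii = NULL) {
  s <- config_points(skull_config)
  n <- normalize_rows(as_pts(directions))
  d <- as.numeric(mean_depths)
  if (length(d) != nrow(s)) stop("depths must be indexed like the skull points")
  miss <- which(is.na(d))
  if (length(miss) == nrow(s)) stop("all depths missing")
  if (length(miss) > 0) {
    have <- which(!is.na(d))
    for (i in miss) {
      dd <- row_norms(s[have, , drop = FALSE] -
                        matrix(s[i, ], length(have), 3, byrow = TRUE))
      ord <- order(dd)[seq_len(min(8, length(have)))]
      w <- 1 / pmax(dd[ord], 1e-9)
      d[i] <- sum(w * d[have][ord]) / sum(w)
    }
  }
  h <- s + n * d
  mesh <- if (!is.null(faces)) cf_mesh(h, faces)
  else reconstruct_surface(h, radii = radii)
  list(points = cf_config(h), mesh = mesh, depths = d, imputed = miss)
}
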
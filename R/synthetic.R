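# Synthetic paired skull/face cohorts with a known FSTD field, known
# inter-individual shape variation, and a tunable linear hard->soft organ
# coupling. The base head is a radius-80 mm sphere modulated by smooth
# low-order angular modes; realism is explicitly a non-goal.

#' Unit icosphere mesh
#'
#' Subdivided icosahedron; subdivision level `s` yields `10*4^s + 2`
#' vertices. Vertices are unit vectors (outward normals of the sphere).
#'
#' @param subdivisions non-negative integer.
#' @return A [cf_mesh()] with unit-length vertices.
#' @export
icosphere <- function(subdivisions = 3L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- normalize_rows(v)
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid_env <- new.env(hash = TRUE)
    nv <- nrow(v)
    verts <- list(v)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (exists(key, envir = mid_env)) return(get(key, envir = mid_env))
      nv <<- nv + 1L
      m <- (v[a, ] + v[b, ]) / 2
      verts[[length(verts) + 1L]] <<- matrix(m / sqrt(sum(m^2)), 1)
      assign(key, nv, envir = mid_env)
      nv
    }
    newf <- matrix(0L, 4 * nrow(f), 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newf[4 * i - 3, ] <- c(a, ab, ca)
      newf[4 * i - 2, ] <- c(b, bc, ab)
      newf[4 * i - 1, ] <- c(c, ca, bc)
      newf[4 * i, ] <- c(ab, bc, ca)
    }
    v <- do.call(rbind, verts)
    f <- newf
  }
  cf_mesh(v, f)
}

# smooth low-order angular modes (harmonic-polynomial flavoured), evaluated
# at unit directions; each returns a zero-mean-ish field of unit-ish scale
head_modes <- function(dirs) {
  x <- dirs[, 1]; y <- dirs[, 2]; z <- dirs[, 3]
  cbind(z,
        x * y,
        x * z,
        (x^2 - y^2),
        (3 * z^2 - 1) / 2,
        y * z,
        x * (x^2 - 3 * y^2) / 2,
        z * (5 * z^2 - 3) / 2)
}

smoothstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t * t * (3 - 2 * t)
}

# raised-cosine window: 1 at the patch centre direction, 0 beyond ang radius
patch_window <- function(dirs, center, ang) {
  cth <- pmin(pmax(as.vector(dirs %*% center), -1), 1)
  theta <- acos(cth)
  smoothstep(1 - theta / ang)
}

#' Specification of a synthetic skull/face cohort
#'
#' @param n specimens (>= 3; default 48 to mirror a typical adult CT cohort).
#' @param seed RNG seed; the cohort is bit-reproducible given the spec+seed.
#' @param radius base head radius (mm).
#' @param subdivisions icosphere level (4 gives 2562 vertices / 5120 faces).
#' @param depth_mean cohort-average soft-tissue depth (mm).
#' @param depth_pattern_amp amplitude of the smooth spatial depth pattern (mm).
#' @param subject_depth_sd per-subject scalar depth offset SD (mm).
#' @param depth_noise_sd per-point depth noise SD (mm).
#' @param shape_mode_sds SDs (mm) of the global head-shape modes.
#' @param organ_q latent dimension of the organ coupling.
#' @param organ_rho hard/soft latent correlation in `[0, 1]`.
#' @param organ_scale displacement scale (mm) of the organ modes.
#' @param organ_noise_sd independent soft-organ noise SD (mm).
#' @return object of class `cf_cohort_spec`.
#' @export
cohort_spec <- function(n = 48L, seed = 1L, radius = 80,
                        subdivisions = 4L, depth_mean = 9,
                        depth_pattern_amp = 1.5, subject_depth_sd = 0.8,
                        depth_noise_sd = 0.3,
                        shape_mode_sds = c(2, 1.5, 1.2, 1, 0.8, 0.6, 0.5, 0.4),
                        organ_q = 2L, organ_rho = 0.8, organ_scale = 1.5,
                        organ_noise_sd = 0.2) {
  if (n < 3) stop("n must be >= 3")
  if (organ_rho < 0 || organ_rho > 1) stop("organ_rho must be in [0, 1]")
  if (any(c(subject_depth_sd, depth_noise_sd, organ_noise_sd,
            shape_mode_sds) < 0)) stop("all SDs must be >= 0")
  if (subdivisions < 2) stop("resolution too low for patch definition")
  structure(as.list(environment()), class = "cf_cohort_spec")
}

cohort_patches <- function() {
  list(nasal = list(center = c(0, 0.95, 0.15) / sqrt(sum(c(0, 0.95, 0.15)^2)),
                    ang = 0.38),
       oral = list(center = c(0, 0.92, -0.32) / sqrt(sum(c(0, 0.92, -0.32)^2)),
                   ang = 0.42))
}

# named landmark directions; Lp/Rp/Lo/G are the Frankfort set
cohort_landmark_dirs <- function() {
  d <- rbind(
    Lp = c(-1, 0, 0), Rp = c(1, 0, 0),
    Lo = c(-0.35, 0.85, -0.12), G = c(0, 0.75, 0.65),
    N1 = c(0, 1, 0.05), N2 = c(0.2, 0.9, 0.35), N3 = c(-0.2, 0.9, 0.35),
    V1 = c(0, 0, 1), V2 = c(0.6, 0.5, 0.6), V3 = c(-0.6, 0.5, 0.6),
    B1 = c(0, -1, 0), B2 = c(0.7, -0.6, 0.3), B3 = c(-0.7, -0.6, 0.3),
    S1 = c(0.9, 0.3, -0.3), S2 = c(-0.9, 0.3, -0.3),
    S3 = c(0.8, -0.2, 0.55), S4 = c(-0.8, -0.2, 0.55),
    M1 = c(0.45, 0.8, -0.4), M2 = c(-0.45, 0.8, -0.4),
    T1 = c(0.3, -0.3, -0.9), T2 = c(-0.3, -0.3, -0.9),
    C1 = c(0, 0.55, -0.83), C2 = c(0.5, 0.1, 0.86), C3 = c(-0.5, 0.1, 0.86),
    D1 = c(0.95, -0.3, 0), D2 = c(-0.95, -0.3, 0),
    E1 = c(0.4, 0.45, 0.8), E2 = c(-0.4, 0.45, 0.8),
    F1 = c(0.85, 0.5, 0.15), F2 = c(-0.85, 0.5, 0.15))
  normalize_rows(d)
}

#' Generate a synthetic paired skull/face cohort
#'
#' Each skull is the smooth base head plus individual shape-mode
#' perturbations, with nasal and oral patches carved at fixed solid angles
#' and displaced by latent organ factors. Each face offsets its skull along
#' the outward radial directions by that subject's depth field; nose and
#' mouth patches are additionally displaced by
#' `rho * shared latent + sqrt(1 - rho^2) * independent` mode coefficients,
#' so the hard-to-soft map is exactly linear when the independent noise is
#' zero. Landmarks sit at fixed parametric directions, guaranteeing perfect
#' cross-specimen homology.
#'
#' @param spec a [cohort_spec()].
#' @return object of class `cf_cohort`: lists `skulls`, `faces`
#'   ([cf_mesh()]es in a common canonical frame), `skull_landmarks`,
#'   `face_landmarks` ([cf_landmarks()]), `skull_labels`, `face_labels`
#'   ([cf_labels()]), `landmark_idx` (named vertex indices), `eval_idx`
#'   (16 + 59 evaluation point indices), `truth` (per-specimen depth fields,
#'   latents, the hard->soft map parameters), and `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cf_cohort_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(spec$seed))
  base <- icosphere(spec$subdivisions)
  dirs <- base$vertices
  nv <- nrow(dirs)
  modes <- head_modes(dirs)
  nmode <- min(ncol(modes), length(spec$shape_mode_sds))
  patches <- cohort_patches()
  w_nasal <- patch_window(dirs, patches$nasal$center, patches$nasal$ang)
  w_oral <- patch_window(dirs, patches$oral$center, patches$oral$ang)
  nasal_idx <- which(w_nasal > 0.05)
  oral_idx <- which(w_oral > 0.05 & w_nasal <= 0.05)
  skull_labels <- rep("envelope", nv)
  skull_labels[nasal_idx] <- "nasal"
  skull_labels[oral_idx] <- "oral"
  face_labels <- sub("^nasal$", "nose", sub("^oral$", "mouth", skull_labels))
  if (length(nasal_idx) < 12 || length(oral_idx) < 12)
    stop("resolution too low for patch definition")
  # base head: sphere + fixed smooth asymmetry, patches slightly carved
  base_r <- spec$radius + 1.5 * modes[, 5] - 2.0 * w_nasal - 1.5 * w_oral
  # smooth depth field with mean ~ depth_mean
  pat <- modes[, 1] * 0.4 + modes[, 4] * 0.3 + modes[, 6] * 0.3
  depth_mu <- spec$depth_mean + spec$depth_pattern_amp * (pat - mean(pat))
  # organ modes: smooth fields supported on each patch
  organ_modes <- function(w) {
    m <- cbind(w, w * dirs[, 1], w * dirs[, 3], w * dirs[, 1] * dirs[, 3])
    m[, seq_len(max(spec$organ_q, 1)), drop = FALSE]
  }
  gn <- organ_modes(w_nasal)
  go <- organ_modes(w_oral)
  q <- spec$organ_q
  lmdirs <- cohort_landmark_dirs()
  landmark_idx <- apply(lmdirs, 1, function(d) which.max(dirs %*% d))
  names(landmark_idx) <- rownames(lmdirs)
  # evaluation scheme: 16 landmarks + 59 spread semilandmarks
  eval_lm <- landmark_idx[seq_len(16)]
  spread <- unique(round(seq(1, nv, length.out = 80)))
  spread <- setdiff(spread, eval_lm)[seq_len(59)]
  eval_idx <- c(eval_lm, spread)
  skulls <- vector("list", spec$n)
  faces <- vector("list", spec$n)
  depth_fields <- matrix(0, spec$n, nv)
  z_nasal <- matrix(stats::rnorm(spec$n * q), spec$n, q)
  z_oral <- matrix(stats::rnorm(spec$n * q), spec$n, q)
  amp <- matrix(stats::rnorm(spec$n * nmode), spec$n, nmode)
  amp <- sweep(amp, 2, spec$shape_mode_sds[seq_len(nmode)], `*`)
  rho <- spec$organ_rho
  for (i in seq_len(spec$n)) {
    r_core <- base_r + as.vector(modes[, seq_len(nmode), drop = FALSE] %*%
                                   amp[i, ])
    # hard organ displacement driven by the latents
    hard_disp <- spec$organ_scale * as.vector(gn %*% z_nasal[i, ]) +
      spec$organ_scale * as.vector(go %*% z_oral[i, ])
    r_hard <- r_core + hard_disp
    skull_v <- dirs * r_hard
    d_i <- depth_mu + stats::rnorm(1, 0, spec$subject_depth_sd) +
      stats::rnorm(nv, 0, spec$depth_noise_sd)
    d_i <- pmax(d_i, 1)
    # soft organ displacement is anchored to the core head and driven by
    # rho-coupled latents, so rho alone sets the hard<->soft covariation
    soft_nasal <- rho * z_nasal[i, ] +
      sqrt(1 - rho^2) * stats::rnorm(q)
    soft_oral <- rho * z_oral[i, ] +
      sqrt(1 - rho^2) * stats::rnorm(q)
    soft_disp <- spec$organ_scale * as.vector(gn %*% soft_nasal) +
      spec$organ_scale * as.vector(go %*% soft_oral) +
      stats::rnorm(nv, 0, spec$organ_noise_sd) * (w_nasal + w_oral > 0.05)
    face_r <- r_core + d_i + soft_disp
    # faces must stay outside their skulls
    total <- pmax(face_r - r_hard, 0.8)
    face_v <- dirs * (r_hard + total)
    depth_fields[i, ] <- total
    skulls[[i]] <- cf_mesh(skull_v, base$faces)
    faces[[i]] <- cf_mesh(face_v, base$faces)
  }
  mk_lm <- function(mesh) cf_landmarks(names(landmark_idx),
                                       mesh$vertices[landmark_idx, ,
                                                     drop = FALSE])
  structure(list(
    skulls = skulls, faces = faces,
    skull_landmarks = lapply(skulls, mk_lm),
    face_landmarks = lapply(faces, mk_lm),
    skull_labels = cf_labels(skull_labels),
    face_labels = cf_labels(face_labels),
    landmark_idx = landmark_idx, eval_idx = eval_idx,
    template_faces = base$faces, directions = dirs,
    truth = list(depth_mu = depth_mu, depth_fields = depth_fields,
                 z_nasal = z_nasal, z_oral = z_oral, rho = rho,
                 organ_scale = spec$organ_scale,
                 nasal_modes = gn, oral_modes = go,
                 shape_amplitudes = amp, head_modes = modes[, seq_len(nmode)]),
    spec = spec), class = "cf_cohort")
}

#' @export
print.cf_cohort <- function(x, ...) {
  cat(sprintf("<cf_cohort> n = %d specimens, %d vertices per mesh\n",
              length(x$skulls), nrow(x$skulls[[1]]$vertices)))
  invisible(x)
}

#' Recovery metrics of pipeline estimates against generator truth
#'
#' Compares estimated quantities with the values the generator used:
#' per-point FSTD means against the true depth field, estimated RV /
#' axis-1 correlation against the latent coupling `rho`, a learned
#' regression map against the ideal linear map (via prediction on the true
#' latents), and an SSM basis against the generating modes (principal
#' subspace angle).
#'
#' @param cohort a [generate_cohort()] result.
#' @param fstd_stats optional [fstd_statistics()] result over the cohort.
#' @param pls optional [two_block_pls()] result for an organ.
#' @param ssm optional [build_ssm()] result.
#' @return list of per-stage recovery tables (only requested stages present).
#' @export
truth_report <- function(cohort, fstd_stats = NULL, pls = NULL, ssm = NULL) {
  out <- list()
  if (!is.null(fstd_stats)) {
    true_mean <- colMeans(cohort$truth$depth_fields)
    err <- fstd_stats$mean - true_mean
    out$fstd <- list(mean_abs_error_mm = mean(abs(err), na.rm = TRUE),
                     max_abs_error_mm = max(abs(err), na.rm = TRUE),
                     q95_abs_error_mm = stats::quantile(abs(err), 0.95,
                                                        na.rm = TRUE,
                                                        names = FALSE))
  }
  if (!is.null(pls)) {
    out$organ <- list(rv = pls$rv, axis1_correlation = pls$correlations[1],
                      true_rho = cohort$truth$rho)
  }
  if (!is.null(ssm)) {
    # principal angle between the SSM subspace and the generating modes
    gen <- cohort$truth$head_modes
    B <- ssm$basis[, seq_len(min(ssm$d, ncol(ssm$basis))), drop = FALSE]
    # expand generator modes to 3n vectors (radial displacement)
    dirs <- cohort$directions
    G <- do.call(cbind, lapply(seq_len(ncol(gen)), function(m)
      flatten_config(dirs * gen[, m])))
    G <- qr.Q(qr(G))
    sv <- svd(crossprod(G, B))
    out$ssm <- list(max_canonical_correlation = max(sv$d),
                    d = ssm$d)
  }
  out
}
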
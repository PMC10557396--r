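# Training of the full facial-approximation model and the coarse-to-fine
# approximation pipeline.

#' Train a facial-approximation model from a corresponded cohort
#'
#' Inputs are per-specimen skull and face configurations in dense
#' correspondence (same point count and ordering; e.g. established by
#' template registration, or by construction for synthetic cohorts), in a
#' common Frankfort-aligned frame. Training computes the average skull and
#' face, the fixed FSTD measurement directions (average-skull vertex
#' normals), cohort FSTD statistics, nose and mouth hard-to-soft regression
#' models, and the facial statistical shape model.
#'
#' @param skull_configs,face_configs lists of `k x 3` matrices.
#' @param template_faces `m x 3` shared triangulation of the configurations.
#' @param skull_labels [cf_labels()] over skull points
#'   (`envelope`/`nasal`/`oral`).
#' @param face_labels [cf_labels()] over face points
#'   (`envelope`/`nose`/`mouth`).
#' @param landmark_idx named integer vector: template vertex index of each
#'   named landmark (must include `Lp`, `Rp`, `Lo`, `G`).
#' @param eval_idx integer indices of the 75 evaluation points.
#' @param cumulative_threshold PC retention threshold for all shape spaces.
#' @param eta ridge weight for the organ regressions (NULL = LOOCV grid).
#' @param max_depth FSTD ray limit (mm).
#' @return object of class `cf_fa_model`.
#' @export
train_fa_model <- function(skull_configs, face_configs, template_faces,
                           skull_labels, face_labels, landmark_idx,
                           eval_idx, cumulative_threshold = 0.95,
                           eta = NULL, max_depth = 60) {
  n <- length(skull_configs)
  if (n < 3) stop("training needs at least 3 specimens")
  if (length(face_configs) != n) stop("skull/face specimen counts differ")
  if (!all(c("Lp", "Rp", "Lo", "G") %in% names(landmark_idx)))
    stop("landmark_idx must name Lp, Rp, Lo and G")
  # bring every specimen pair into the common Frankfort frame first
  for (i in seq_len(n)) {
    s <- skull_configs[[i]]
    fa <- frankfort_align(NULL, s[landmark_idx[["Lp"]], ],
                          s[landmark_idx[["Rp"]], ],
                          s[landmark_idx[["Lo"]], ],
                          s[landmark_idx[["G"]], ])
    skull_configs[[i]] <- fa$transform(s)
    face_configs[[i]] <- fa$transform(face_configs[[i]])
  }
  avg_skull_pts <- Reduce(`+`, skull_configs) / n
  avg_skull <- compute_vertex_normals(cf_mesh(avg_skull_pts, template_faces))
  directions <- avg_skull$normals
  fields <- lapply(seq_len(n), function(i)
    measure_fstd(skull_configs[[i]], directions,
                 cf_mesh(face_configs[[i]], template_faces),
                 max_depth = max_depth))
  stats <- fstd_statistics(fields)
  nasal_idx <- which(skull_labels$labels == "nasal")
  oral_idx <- which(skull_labels$labels == "oral")
  nose_idx <- which(face_labels$labels == "nose")
  mouth_idx <- which(face_labels$labels == "mouth")
  env_idx <- which(skull_labels$labels == "envelope")
  sub_cfg <- function(cfgs, idx) lapply(cfgs, function(p)
    p[idx, , drop = FALSE])
  nose_model <- fit_organ_model(sub_cfg(skull_configs, nasal_idx),
                                sub_cfg(face_configs, nose_idx),
                                eta = eta,
                                cumulative_threshold = cumulative_threshold)
  mouth_model <- fit_organ_model(sub_cfg(skull_configs, oral_idx),
                                 sub_cfg(face_configs, mouth_idx),
                                 eta = eta,
                                 cumulative_threshold = cumulative_threshold)
  ssm <- build_ssm(face_configs, cumulative_threshold)
  avg_face_pts <- Reduce(`+`, face_configs) / n
  env_sub <- component_submesh(avg_skull, skull_labels, "envelope")
  # triangulation of the envelope points, indexed into env_idx order
  env_faces <- matrix(match(env_sub$vertex_index[env_sub$mesh$faces],
                            env_idx), ncol = 3)
  nose_sub <- component_submesh(cf_mesh(avg_face_pts, template_faces),
                                face_labels, "nose")
  mouth_sub <- component_submesh(cf_mesh(avg_face_pts, template_faces),
                                 face_labels, "mouth")
  structure(list(
    avg_skull = avg_skull, avg_face = avg_face_pts,
    directions = directions, fstd = stats,
    nose_model = nose_model, mouth_model = mouth_model, ssm = ssm,
    template_faces = template_faces,
    skull_labels = skull_labels, face_labels = face_labels,
    landmark_idx = landmark_idx, eval_idx = eval_idx,
    env_idx = env_idx, nasal_idx = nasal_idx, oral_idx = oral_idx,
    nose_idx = nose_idx, mouth_idx = mouth_idx,
    env_faces = env_faces,
    nose_faces = matrix(match(nose_sub$vertex_index[nose_sub$mesh$faces],
                              which(face_labels$labels == "nose")), ncol = 3),
    mouth_faces = matrix(match(mouth_sub$vertex_index[mouth_sub$mesh$faces],
                               which(face_labels$labels == "mouth")),
                         ncol = 3),
    n_train = n), class = "cf_fa_model")
}

#' @export
print.cf_fa_model <- function(x, ...) {
  cat(sprintf(paste0("<cf_fa_model> trained on %d specimens; %d skull ",
                     "points (%d envelope), SSM d = %d\n"),
              x$n_train, nrow(x$avg_skull$vertices), length(x$env_idx),
              x$ssm$d))
  invisible(x)
}

#' Approximate a face from a dry skull
#'
#' Coarse-to-fine pipeline: Frankfort alignment; hybrid TPS+NICP
#' registration of the average skull onto the dry skull; projection of the
#' dense semilandmarks; envelope generation from average FSTDs; nose and
#' mouth prediction by shape regression; boundary-curve placement of the
#' organs on the deformed average facial envelope; SSM fitting to the
#' transformed coarse face (filling eyes/ears/missing regions); Laplacian
#' refinement towards the coarse soft tissues. All intermediates are
#' returned for audit.
#'
#' @param dry_skull a [cf_mesh()] of the dry skull.
#' @param dry_landmarks a [cf_landmarks()] naming at least the model's
#'   landmark set (including `Lp`, `Rp`, `Lo`, `G`).
#' @param model a [train_fa_model()] result.
#' @param stiffness_schedule,max_iter NICP controls.
#' @param lambda SSM ridge weight (NULL = `1e-3 *` leading eigenvalue).
#' @param anchor_weight Laplacian anchor weight.
#' @param tps_controls number of TPS control points for warping the average
#'   face (subsampled from the dense correspondence).
#' @return object of class `cf_approx_face`: `mesh` and `config` (the
#'   refined face, Frankfort frame of the dry skull), plus intermediates
#'   (`skull_config`, `envelope`, `nose`, `mouth`, `deformed_avg_face`,
#'   `ssm_fit`, `frankfort`, `registration`, `ssm_transform`).
#' @export
approximate_face <- function(dry_skull, dry_landmarks, model,
                             stiffness_schedule = c(20, 8, 2),
                             max_iter = 4L, lambda = NULL,
                             anchor_weight = 1, tps_controls = 250L) {
  get_lm <- function(nm) {
    i <- match(nm, dry_landmarks$names)
    if (is.na(i))
      stop("stage frankfort_align: landmark '", nm, "' missing")
    dry_landmarks$points[i, ]
  }
  fa <- frankfort_align(dry_skull, get_lm("Lp"), get_lm("Rp"),
                        get_lm("Lo"), get_lm("G"))
  skull_al <- fa$mesh
  lm_names <- intersect(names(model$landmark_idx), dry_landmarks$names)
  if (length(lm_names) < 4)
    stop("stage registration: fewer than 4 usable landmarks")
  dst <- fa$transform(dry_landmarks$points[match(lm_names,
                                                 dry_landmarks$names), ,
                                           drop = FALSE])
  reg <- hybrid_register(model$avg_skull, skull_al,
                         landmark_pairs = list(
                           src_idx = model$landmark_idx[lm_names],
                           dst = dst),
                         stiffness_schedule = stiffness_schedule,
                         max_iter = max_iter)
  cfg <- config_points(project_semilandmarks(reg$mesh$vertices, skull_al))
  env_idx <- model$env_idx
  env <- build_envelope(cfg[env_idx, , drop = FALSE],
                        model$directions[env_idx, , drop = FALSE],
                        model$fstd$mean[env_idx],
                        faces = model$env_faces)
  nose_pred <- predict_organ(model$nose_model,
                             cfg[model$nasal_idx, , drop = FALSE])
  mouth_pred <- predict_organ(model$mouth_model,
                              cfg[model$oral_idx, , drop = FALSE])
  # deformed average face: TPS carrying the average skull onto the dry skull
  k <- nrow(cfg)
  ctrl <- unique(round(seq(1, k, length.out = min(tps_controls, k))))
  warp <- tps_fit(model$avg_skull$vertices[ctrl, , drop = FALSE],
                  cfg[ctrl, , drop = FALSE])
  def_face_pts <- tps_apply(warp, model$avg_face)
  def_face <- cf_mesh(def_face_pts, model$template_faces)
  nose_placed <- place_component(
    list(points = nose_pred, faces = model$nose_faces),
    def_face, model$face_labels, "nose")
  mouth_placed <- place_component(
    list(points = mouth_pred, faces = model$mouth_faces),
    def_face, model$face_labels, "mouth")
  tssm <- transform_to_ssm_frame(cfg[env_idx, , drop = FALSE],
                                 model$directions[env_idx, , drop = FALSE],
                                 config_points(env$points), def_face,
                                 model$ssm$mean)
  tp_ssm <- similarity_apply(tssm$transform, tssm$pts)
  keep <- !duplicated(tssm$idx)
  fit <- fit_ssm(model$ssm, tssm$idx[keep], tp_ssm[keep, , drop = FALSE],
                 lambda = lambda)
  q_mesh <- cf_mesh(fit$face, model$template_faces)
  nose_ssm <- similarity_apply(tssm$transform, nose_placed$points)
  mouth_ssm <- similarity_apply(tssm$transform, mouth_placed$points)
  anchor_idx <- c(tssm$idx[keep], model$nose_idx, model$mouth_idx)
  anchor_pts <- rbind(tp_ssm[keep, , drop = FALSE], nose_ssm, mouth_ssm)
  first <- !duplicated(anchor_idx)
  refined <- laplacian_refine(q_mesh, anchor_idx[first],
                              anchor_pts[first, , drop = FALSE],
                              weight = anchor_weight)
  # back to the dry skull's Frankfort frame
  inv <- similarity_invert(tssm$transform)
  final_pts <- similarity_apply(inv, refined$mesh$vertices)
  final_mesh <- cf_mesh(final_pts, model$template_faces)
  structure(list(
    mesh = final_mesh, config = final_pts,
    skull_config = cfg, envelope = env,
    nose = nose_placed, mouth = mouth_placed,
    deformed_avg_face = def_face, ssm_fit = fit,
    refined_ssm_frame = refined, frankfort = fa,
    registration = list(tps_residual = reg$tps_residual,
                        nicp_residual = reg$nicp_residual),
    ssm_transform = tssm$transform), class = "cf_approx_face")
}

#' @export
print.cf_approx_face <- function(x, ...) {
  cat(sprintf(paste0("<cf_approx_face> %d vertices; registration residual ",
                     "%.3f mm\n"), nrow(x$config),
              x$registration$nicp_residual))
  invisible(x)
}
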
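# Text-based trained-model archive: a versioned directory of CSV/JSON/PLY
# files with a manifest, so trained models can be shipped and used from the
# command line without binary formats.

write_mat <- function(m, path) {
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
read_mat <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE))
}

save_shape_space <- function(sp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mat(sp$mean, file.path(dir, "mean.csv"))
  write_mat(sp$basis, file.path(dir, "basis.csv"))
  write_mat(cbind(sp$eigenvalues), file.path(dir, "eigenvalues.csv"))
  jsonlite::write_json(list(d = sp$d), file.path(dir, "meta.json"),
                       auto_unbox = TRUE)
}
load_shape_space <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  structure(list(mean = unname(read_mat(file.path(dir, "mean.csv"))),
                 basis = unname(read_mat(file.path(dir, "basis.csv"))),
                 eigenvalues = as.vector(read_mat(
                   file.path(dir, "eigenvalues.csv"))),
                 d = as.integer(meta$d)),
            class = "cf_shapespace")
}

save_organ_model <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  save_shape_space(m$hard_space, file.path(dir, "hard"))
  save_shape_space(m$soft_space, file.path(dir, "soft"))
  write_mat(m$M, file.path(dir, "M.csv"))
  jsonlite::write_json(list(eta = m$eta,
                            with_scaling = isTRUE(m$with_scaling)),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
}
load_organ_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  structure(list(hard_space = load_shape_space(file.path(dir, "hard")),
                 soft_space = load_shape_space(file.path(dir, "soft")),
                 M = unname(read_mat(file.path(dir, "M.csv"))),
                 eta = meta$eta, with_scaling = meta$with_scaling),
            class = "cf_organ_model")
}

#' Save a trained facial-approximation model as a text archive
#'
#' Writes a versioned directory (manifest + CSV/JSON/PLY files) holding the
#' average skull and face, FSTD statistics, both organ models, the facial
#' SSM and all bookkeeping needed by [approximate_face()].
#'
#' @param model a [train_fa_model()] result.
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_fa_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mesh(model$avg_skull, file.path(dir, "avg_skull.ply"),
             binary = FALSE)
  write_mat(model$avg_face, file.path(dir, "avg_face.csv"))
  write_mat(model$directions, file.path(dir, "directions.csv"))
  utils::write.csv(data.frame(mean_depth_mm = model$fstd$mean,
                              sd_mm = model$fstd$sd,
                              n_available = model$fstd$n_available),
                   file.path(dir, "fstd.csv"), row.names = FALSE)
  save_organ_model(model$nose_model, file.path(dir, "nose"))
  save_organ_model(model$mouth_model, file.path(dir, "mouth"))
  ssm <- model$ssm
  dir.create(file.path(dir, "ssm"), showWarnings = FALSE)
  write_mat(ssm$mean, file.path(dir, "ssm", "mean.csv"))
  write_mat(ssm$basis, file.path(dir, "ssm", "basis.csv"))
  write_mat(cbind(ssm$eigenvalues), file.path(dir, "ssm",
                                              "eigenvalues.csv"))
  jsonlite::write_json(list(d = ssm$d), file.path(dir, "ssm", "meta.json"),
                       auto_unbox = TRUE)
  write_mat(model$template_faces, file.path(dir, "template_faces.csv"))
  utils::write.csv(data.frame(vertex_index = seq_along(
                                model$skull_labels$labels),
                              skull = model$skull_labels$labels,
                              face = model$face_labels$labels),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(format = "cranioface-fa-model", version = 1,
         n_train = model$n_train,
         landmark_idx = as.list(model$landmark_idx),
         eval_idx = model$eval_idx,
         cohort_fstd_mean = model$fstd$cohort_mean,
         cohort_fstd_sd = model$fstd$cohort_sd),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a trained facial-approximation model archive
#' @param dir directory written by [save_fa_model()].
#' @return a `cf_fa_model`.
#' @export
load_fa_model <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  if (!identical(man$format, "cranioface-fa-model"))
    stop("not a cranioface model archive: ", dir)
  avg_skull <- read_mesh(file.path(dir, "avg_skull.ply"))
  template_faces <- unname(read_mat(file.path(dir, "template_faces.csv")))
  storage.mode(template_faces) <- "integer"
  fstd_df <- utils::read.csv(file.path(dir, "fstd.csv"))
  labels <- utils::read.csv(file.path(dir, "labels.csv"),
                            stringsAsFactors = FALSE)
  skull_labels <- cf_labels(labels$skull)
  face_labels <- cf_labels(labels$face)
  directions <- unname(read_mat(file.path(dir, "directions.csv")))
  fstd <- structure(list(mean = fstd_df$mean_depth_mm, sd = fstd_df$sd_mm,
                         n_available = fstd_df$n_available,
                         cohort_mean = man$cohort_fstd_mean,
                         cohort_sd = man$cohort_fstd_sd,
                         directions = directions),
                    class = "cf_fstd_stats")
  ssm_meta <- jsonlite::read_json(file.path(dir, "ssm", "meta.json"),
                                  simplifyVector = TRUE)
  ssm <- structure(list(mean = unname(read_mat(file.path(dir, "ssm",
                                                         "mean.csv"))),
                        basis = unname(read_mat(file.path(dir, "ssm",
                                                          "basis.csv"))),
                        eigenvalues = as.vector(read_mat(
                          file.path(dir, "ssm", "eigenvalues.csv"))),
                        d = as.integer(ssm_meta$d)),
                   class = "cf_ssm")
  landmark_idx <- unlist(man$landmark_idx)
  avg_face <- unname(read_mat(file.path(dir, "avg_face.csv")))
  env_idx <- which(skull_labels$labels == "envelope")
  env_sub <- component_submesh(avg_skull, skull_labels, "envelope")
  env_faces <- matrix(match(env_sub$vertex_index[env_sub$mesh$faces],
                            env_idx), ncol = 3)
  nose_sub <- component_submesh(cf_mesh(avg_face, template_faces),
                                face_labels, "nose")
  mouth_sub <- component_submesh(cf_mesh(avg_face, template_faces),
                                 face_labels, "mouth")
  structure(list(
    avg_skull = avg_skull, avg_face = avg_face, directions = directions,
    fstd = fstd,
    nose_model = load_organ_model(file.path(dir, "nose")),
    mouth_model = load_organ_model(file.path(dir, "mouth")),
    ssm = ssm, template_faces = template_faces,
    skull_labels = skull_labels, face_labels = face_labels,
    landmark_idx = landmark_idx, eval_idx = as.integer(man$eval_idx),
    env_idx = env_idx,
    nasal_idx = which(skull_labels$labels == "nasal"),
    oral_idx = which(skull_labels$labels == "oral"),
    nose_idx = which(face_labels$labels == "nose"),
    mouth_idx = which(face_labels$labels == "mouth"),
    env_faces = env_faces,
    nose_faces = matrix(match(nose_sub$vertex_index[nose_sub$mesh$faces],
                              which(face_labels$labels == "nose")),
                        ncol = 3),
    mouth_faces = matrix(match(mouth_sub$vertex_index[mouth_sub$mesh$faces],
                               which(face_labels$labels == "mouth")),
                         ncol = 3),
    n_train = man$n_train), class = "cf_fa_model")
}
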
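# Resemblance metrics, top-k recognition, and the end-to-end LOOCV driver.

#' Resemblance between an approximated and an actual face
#'
#' Superimposes the two faces on their evaluation configurations (16
#' landmarks + 59 semilandmarks by convention), applies the fitted transform
#' to the full approximated mesh, and reports (i) the Procrustes distance of
#' the evaluation configurations, (ii) the mean dense Euclidean distance
#' from the approximated vertices to the nearest points on the actual
#' surface (directional, in mm), and (iii) the per-vertex deviation field.
#'
#' @param approx,actual [cf_mesh()]es.
#' @param eval_approx,eval_actual `75 x 3` (or matching) evaluation
#'   configurations on each face.
#' @param with_scaling allow scaling in the superimposition and the
#'   Procrustes distance (default FALSE: form-space comparison in mm).
#' @return list: `procrustes`, `dense_mm`, `deviation` (per approx vertex),
#'   `transform`.
#' @export
resemblance <- function(approx, actual, eval_approx, eval_actual,
                        with_scaling = FALSE) {
  ea <- as_pts(eval_approx); et <- as_pts(eval_actual)
  if (nrow(ea) != nrow(et)) stop("evaluation point counts differ")
  if (anyNA(ea) || anyNA(et)) stop("missing evaluation points")
  tf <- similarity_align(ea, et, with_scaling = with_scaling)
  moved <- similarity_apply(tf, approx$vertices)
  cp <- cf_closest_points_mesh(moved, actual$vertices, actual$faces)
  list(procrustes = procrustes_distance(ea, et, with_scaling = with_scaling),
       dense_mm = mean(cp[, 4]), deviation = cp[, 4], transform = tf)
}

#' Top-k recognition rate
#'
#' Ranks every face in the pool by ascending Procrustes distance to each
#' approximation (ties broken by pool index); a hit means the true
#' counterpart ranks within the top k. The rate is `100 * hits / n`.
#'
#' @param approx_evals list of evaluation configurations of the
#'   approximated faces.
#' @param pool_evals list of evaluation configurations of the actual faces;
#'   `pool_evals[[i]]` is the true counterpart of `approx_evals[[i]]`.
#' @param k rank threshold (>= 1).
#' @param with_scaling passed to [procrustes_distance()].
#' @param truth_idx pool index of each approximation's true counterpart
#'   (default: position-wise).
#' @return list: `rate` (percent), `ranks` (per specimen), `hits`.
#' @export
recognition_rate <- function(approx_evals, pool_evals, k = 1L,
                             with_scaling = FALSE,
                             truth_idx = seq_along(approx_evals)) {
  n <- length(approx_evals)
  if (length(pool_evals) < n || any(truth_idx > length(pool_evals)))
    stop("pool must contain each approximation's true counterpart")
  if (k < 1 || k > length(pool_evals)) stop("k must be in 1..|pool|")
  flat <- vapply(pool_evals, function(p)
    paste(signif(as_pts(p), 12), collapse = ","), "")
  if (anyDuplicated(flat))
    warning("duplicate pool entries; first occurrence used for ranking")
  ranks <- integer(n)
  for (i in seq_len(n)) {
    d <- vapply(pool_evals, function(p)
      procrustes_distance(approx_evals[[i]], p, with_scaling = with_scaling),
      0)
    ord <- order(d)  # stable: ties broken by pool index
    ranks[i] <- which(ord == truth_idx[i])
  }
  hits <- sum(ranks <= k)
  list(rate = 100 * hits / n, ranks = ranks, hits = hits)
}

#' End-to-end leave-one-out cross-validation of the approximation pipeline
#'
#' For each specimen, trains the full model ([train_fa_model()]) on the
#' remaining specimens, runs [approximate_face()] on the held-out dry skull,
#' and evaluates the result against the held-out actual face. Also evaluates
#' the trivial cohort-mean-face predictor as a baseline, and the top-k
#' recognition rate over the pool of actual faces.
#'
#' @param cohort a [generate_cohort()] result (or a list with the same
#'   fields).
#' @param k recognition rank threshold.
#' @param mm_thresholds dense-error thresholds (mm) for which the fraction
#'   of specimens below each is reported.
#' @param cumulative_threshold,eta passed to [train_fa_model()].
#' @param stiffness_schedule,max_iter passed to [approximate_face()].
#' @param specimens optional subset of specimen indices to hold out.
#' @return object of class `cf_loocv_report`: `table` (per-specimen
#'   data.frame: procrustes, dense_mm, baseline_dense_mm, rank, error),
#'   `recognition` (percent top-k), `mean_dense_mm`, `mean_procrustes`,
#'   `beats_baseline` (fraction), `fraction_under` (per threshold).
#' @export
pipeline_loocv <- function(cohort, k = 1L, mm_thresholds = c(1, 2),
                           cumulative_threshold = 0.95, eta = NULL,
                           stiffness_schedule = c(20, 8, 2),
                           max_iter = 4L, specimens = NULL) {
  n <- length(cohort$skulls)
  if (n < 4) stop("cohort must have at least 4 specimens")
  specimens <- specimens %||% seq_len(n)
  skull_cfgs <- lapply(cohort$skulls, `[[`, "vertices")
  face_cfgs <- lapply(cohort$faces, `[[`, "vertices")
  eval_idx <- cohort$eval_idx
  rows <- vector("list", length(specimens))
  approx_evals <- vector("list", length(specimens))
  pool_evals <- lapply(face_cfgs, function(p) p[eval_idx, , drop = FALSE])
  for (j in seq_along(specimens)) {
    i <- specimens[j]
    row <- list(specimen = i, procrustes = NA_real_, dense_mm = NA_real_,
                baseline_dense_mm = NA_real_, error = NA_character_)
    res <- tryCatch({
      model <- train_fa_model(skull_cfgs[-i], face_cfgs[-i],
                              cohort$template_faces, cohort$skull_labels,
                              cohort$face_labels, cohort$landmark_idx,
                              eval_idx,
                              cumulative_threshold = cumulative_threshold,
                              eta = eta)
      ap <- approximate_face(cohort$skulls[[i]],
                             cohort$skull_landmarks[[i]], model,
                             stiffness_schedule = stiffness_schedule,
                             max_iter = max_iter)
      actual <- cohort$faces[[i]]
      rs <- resemblance(ap$mesh, actual,
                        ap$config[eval_idx, , drop = FALSE],
                        face_cfgs[[i]][eval_idx, , drop = FALSE])
      base_mesh <- cf_mesh(model$avg_face, cohort$template_faces)
      rb <- resemblance(base_mesh, actual,
                        model$avg_face[eval_idx, , drop = FALSE],
                        face_cfgs[[i]][eval_idx, , drop = FALSE])
      list(ap = ap, rs = rs, rb = rb)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      row$error <- conditionMessage(res)
    } else {
      row$procrustes <- res$rs$procrustes
      row$dense_mm <- res$rs$dense_mm
      row$baseline_dense_mm <- res$rb$dense_mm
      approx_evals[[j]] <- res$ap$config[eval_idx, , drop = FALSE]
    }
    rows[[j]] <- row
  }
  tab <- do.call(rbind, lapply(rows, function(r)
    data.frame(specimen = r$specimen, procrustes = r$procrustes,
               dense_mm = r$dense_mm,
               baseline_dense_mm = r$baseline_dense_mm,
               error = r$error %||% NA_character_,
               stringsAsFactors = FALSE)))
  ok <- which(!vapply(approx_evals, is.null, TRUE))
  rec <- if (length(ok) > 0)
    recognition_rate(approx_evals[ok],
                     pool_evals[specimens],
                     k = min(k, length(specimens)),
                     truth_idx = ok)
  else list(rate = NA_real_, ranks = integer(0), hits = 0L)
  tab$rank <- NA_integer_
  tab$rank[ok] <- rec$ranks
  frac_under <- vapply(mm_thresholds, function(th)
    mean(tab$dense_mm[ok] < th), 0)
  names(frac_under) <- paste0("<", mm_thresholds, "mm")
  structure(list(table = tab, recognition = rec$rate,
                 mean_dense_mm = mean(tab$dense_mm, na.rm = TRUE),
                 mean_procrustes = mean(tab$procrustes, na.rm = TRUE),
                 beats_baseline = mean(tab$dense_mm[ok] <
                                         tab$baseline_dense_mm[ok]),
                 fraction_under = frac_under, k = k),
            class = "cf_loocv_report")
}

#' @export
print.cf_loocv_report <- function(x, ...) {
  cat(sprintf(paste0("<cf_loocv_report> n = %d | top-%d recognition %.1f%%",
                     " | mean dense %.2f mm | mean Procrustes %.4f | beats",
                     " baseline %.0f%%\n"),
              nrow(x$table), x$k, x$recognition, x$mean_dense_mm,
              x$mean_procrustes, 100 * x$beats_baseline))
  invisible(x)
}
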
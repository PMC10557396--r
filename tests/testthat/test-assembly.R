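# component placement, SSM construction/fitting, Laplacian refinement,
# and the assembled approximation pipeline

test_that("component placement recovers similarity transforms from loops", {
  co <- std_cohort()
  face <- co$faces[[1]]
  nose_idx <- which(co$face_labels$labels == "nose")
  sub <- component_submesh(face, co$face_labels, "nose")
  comp_pts <- sub$mesh$vertices
  comp <- list(points = comp_pts, faces = sub$mesh$faces)

  # component already in place: near-identity transform
  pl <- place_component(comp, face, co$face_labels, "nose",
                        prescale = "none")
  expect_lt(abs(pl$transform$s - 1), 1e-6)
  expect_lt(max(abs(pl$transform$t)), 1e-4)
  expect_lt(pl$boundary_rms, 1e-6)

  # scaled + translated copy is brought back onto the rim
  moved <- comp
  moved$points <- 0.5 * comp_pts + matrix(c(30, -10, 5), nrow(comp_pts), 3,
                                          byrow = TRUE)
  pl2 <- place_component(moved, face, co$face_labels, "nose",
                         prescale = "none")
  expect_equal(pl2$transform$s, 2, tolerance = 1e-6)
  expect_lt(pl2$boundary_rms, 1e-6)
  expect_lte(pl2$boundary_rms, pl2$initial_rms)
  expect_lt(max(abs(pl2$points - comp_pts)), 1e-4)

  expect_error(place_component(comp, face, co$face_labels, "nose", m = 2),
               "at least 3")
  pl3 <- place_component(moved, face, co$face_labels, "nose", m = 3)
  expect_s3_class(pl3$transform, "cf_similarity")
})

test_that("SSM construction spans the training set", {
  co <- std_cohort()
  cfgs <- lapply(co$faces, `[[`, "vertices")

  same <- rep(cfgs[1], 4)
  s0 <- build_ssm(same)
  expect_equal(s0$d, 0L)
  expect_lt(procrustes_distance(s0$mean, cfgs[[1]]), 1e-8)

  ssm <- build_ssm(cfgs, cumulative_threshold = 1)
  # orthonormal basis
  expect_lt(max(abs(crossprod(ssm$basis) - diag(ncol(ssm$basis)))), 1e-8)
  # training-face reconstruction at full rank
  rec <- ssm_face(ssm, ssm$scores[3, ])
  g <- gpa(cfgs, with_scaling = TRUE)
  expect_lt(max(abs(rec - g$aligned[[3]])), 1e-6)
  expect_error(build_ssm(cfgs[1:2]), "at least 3")

  # 3-mode synthetic population: top-3 modes capture >= 95% variance
  # variation modest relative to size, so GPA alignment stays near-linear
  cfg3 <- factor_configs(50, k = 20, q = 3, sds = c(0.8, 0.5, 0.3),
                         noise = 0.01, seed = 31)
  s3 <- build_ssm(cfg3, cumulative_threshold = 0.95)
  cum3 <- sum(s3$eigenvalues[1:3]) / sum(s3$eigenvalues)
  expect_gte(cum3, 0.95)
})

test_that("SSM fitting is exact, shrinks, and handles partial data", {
  co <- std_cohort()
  cfgs <- lapply(co$faces, `[[`, "vertices")
  ssm <- build_ssm(cfgs, cumulative_threshold = 1)
  g <- gpa(cfgs, with_scaling = TRUE)
  n_pts <- nrow(ssm$mean)

  # full correspondences, lambda = 0: recover the training scores
  fit <- fit_ssm(ssm, seq_len(n_pts), g$aligned[[2]], lambda = 0,
                 d = ncol(ssm$basis))
  expect_lt(max(abs(fit$beta - ssm$scores[2, ])), 1e-6)
  expect_lt(max(abs(fit$face - g$aligned[[2]])), 1e-6)

  # lambda -> infinity: collapse to the mean face
  fit_inf <- fit_ssm(ssm, seq_len(n_pts), g$aligned[[2]], lambda = 1e9)
  expect_lt(max(abs(fit_inf$beta)), 1e-9)
  expect_lt(max(abs(fit_inf$face - ssm$mean)), 1e-9)

  # partial correspondences: beta recovery vs a dense normal-equation oracle
  set.seed(32)
  d <- ssm$d
  beta_star <- stats::rnorm(d) * sqrt(ssm$eigenvalues[seq_len(d)])
  synth <- ssm_face(ssm, beta_star)
  idx <- sort(sample.int(n_pts, round(0.3 * n_pts)))
  lam <- 1e-4
  fit_p <- fit_ssm(ssm, idx, synth[idx, ], lambda = lam, d = d)
  rel <- sqrt(sum((fit_p$beta - beta_star)^2) / sum(beta_star^2))
  expect_lt(rel, 0.05)
  rows <- as.vector(rbind(3 * (idx - 1) + 1, 3 * (idx - 1) + 2,
                          3 * (idx - 1) + 3))
  Us <- ssm$basis[rows, seq_len(d)]
  rhs <- as.vector(t(synth[idx, ])) - as.vector(t(ssm$mean))[rows]
  oracle <- solve(crossprod(Us) + diag(lam^2, d), crossprod(Us, rhs))
  expect_lt(max(abs(fit_p$beta - as.vector(oracle))), 1e-10)

  # objective at the fit never exceeds the objective at beta = 0
  obj0 <- sum((synth[idx, ] - ssm$mean[idx, ])^2)
  expect_lte(fit_p$objective, obj0 + 1e-12)

  # Eq-6 linearity of the reconstruction map
  b1 <- stats::rnorm(d); b2 <- stats::rnorm(d)
  lhs <- ssm_face(ssm, b1 + b2) - ssm$mean
  rhs2 <- (ssm_face(ssm, b1) - ssm$mean) + (ssm_face(ssm, b2) - ssm$mean)
  expect_lt(max(abs(lhs - rhs2)), 1e-10)
  expect_error(fit_ssm(ssm, integer(0), matrix(0, 0, 3)), "empty")
})

test_that("Laplacian refinement solves Eq-7 exactly", {
  m <- sphere_mesh(3, 40)
  n <- nrow(m$vertices)
  anchors <- seq(1, n, by = 7)

  # self-anchors: fixed point
  r0 <- laplacian_refine(m, anchors, m$vertices[anchors, ])
  expect_lt(max(abs(r0$mesh$vertices - m$vertices)), 1e-8)
  expect_identical(r0$mesh$faces, m$faces)

  # translated anchors: whole mesh translates (translation invariance)
  t3 <- c(3, 0, 0)
  r1 <- laplacian_refine(m, anchors,
                         m$vertices[anchors, ] +
                           matrix(t3, length(anchors), 3, byrow = TRUE))
  expect_lt(max(abs(r1$mesh$vertices - sweep(m$vertices, 2, -t3))), 1e-6)

  # random sparse anchors: match a dense normal-equation solve
  set.seed(33)
  a2 <- sort(sample.int(n, 40))
  target <- m$vertices[a2, ] + matrix(stats::rnorm(120), 40, 3)
  w <- 2.5
  r2 <- laplacian_refine(m, a2, target, weight = w)
  L <- as.matrix(mesh_laplacian(m))
  S <- matrix(0, 40, n); S[cbind(1:40, a2)] <- 1
  A <- rbind(L, w * S)
  B <- rbind(L %*% m$vertices, w * target)
  dense <- solve(crossprod(A), crossprod(A, B))
  expect_lt(max(abs(r2$mesh$vertices - dense)), 1e-8)

  # anchor residual decreases monotonically with the weight
  res_w <- vapply(c(0.5, 1, 5, 50, 1000), function(wk)
    laplacian_refine(m, a2, target, weight = wk)$anchor_residual, 0)
  expect_false(is.unsorted(-res_w))
  expect_error(laplacian_refine(m, integer(0), matrix(0, 0, 3)), "anchor")

  # cotangent weights also reproduce the fixed point
  rc <- laplacian_refine(m, anchors, m$vertices[anchors, ],
                         laplacian = "cotangent")
  expect_lt(max(abs(rc$mesh$vertices - m$vertices)), 1e-6)
})

test_that("transform_to_ssm_frame recovers a known frame offset", {
  co <- std_cohort()
  face <- co$faces[[1]]
  dirs <- normalize_rows(icosphere(3)$vertices)
  skull_pts <- co$skulls[[1]]$vertices
  env_idx <- which(co$skull_labels$labels == "envelope")
  # take the true face points as both the "coarse envelope" and the SSM
  # points, expressed in an offset frame
  s <- 0.013
  R <- rot_z(0.4)
  ssm_pts <- s * face$vertices %*% t(R)
  f <- measure_fstd(skull_pts[env_idx, , drop = FALSE],
                    dirs[env_idx, , drop = FALSE], face)
  ok <- which(!is.na(f$depths))
  tr <- transform_to_ssm_frame(f$skull[ok, , drop = FALSE],
                               f$directions[ok, , drop = FALSE],
                               f$face_points[ok, , drop = FALSE],
                               face, ssm_pts)
  expect_lt(abs(tr$transform$s - s), 1e-6)
  expect_lt(max(abs(tr$transform$R - R)), 1e-4)
  moved <- similarity_apply(tr$transform, tr$pts)
  expect_lt(mean(row_norms(moved - ssm_pts[tr$idx, ])), 1e-3)
})

test_that("approximate_face is deterministic and reports stage errors", {
  co <- std_cohort()
  skulls <- lapply(co$skulls, `[[`, "vertices")
  facesv <- lapply(co$faces, `[[`, "vertices")
  model <- train_fa_model(skulls[-1], facesv[-1], co$template_faces,
                          co$skull_labels, co$face_labels, co$landmark_idx,
                          co$eval_idx)
  ap1 <- approximate_face(co$skulls[[1]], co$skull_landmarks[[1]], model)
  ap2 <- approximate_face(co$skulls[[1]], co$skull_landmarks[[1]], model)
  expect_identical(ap1$config, ap2$config)

  # missing G: error names the stage
  lm <- co$skull_landmarks[[1]]
  noG <- cf_landmarks(lm$names[lm$names != "G"],
                      lm$points[lm$names != "G", ])
  expect_error(approximate_face(co$skulls[[1]], noG, model),
               "frankfort_align.*'G'")

  # end-to-end equivariance: a rigidly moved skull yields the same face
  set.seed(34)
  R <- rand_rotation(); t <- c(11, -4, 6)
  moved <- co$skulls[[1]]
  moved$vertices <- moved$vertices %*% t(R) +
    matrix(t, nrow(moved$vertices), 3, byrow = TRUE)
  mlm <- cf_landmarks(lm$names, lm$points %*% t(R) +
                        matrix(t, nrow(lm$points), 3, byrow = TRUE))
  ap3 <- approximate_face(moved, mlm, model)
  expect_lt(mean(row_norms(ap3$config - ap1$config)), 1e-5)

  # oracle setting: training skull beats the cohort-mean face
  rs <- resemblance(ap1$mesh, co$faces[[1]],
                    ap1$config[co$eval_idx, ], facesv[[1]][co$eval_idx, ])
  rb <- resemblance(cf_mesh(model$avg_face, co$template_faces),
                    co$faces[[1]], model$avg_face[co$eval_idx, ],
                    facesv[[1]][co$eval_idx, ])
  expect_lt(rs$dense_mm, rb$dense_mm)
})
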
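# FSTD measurement/statistics/envelope and organ regression

test_that("FSTD measurement is exact on analytic fixtures", {
  sph <- sphere_mesh(3)
  dirs <- icosphere(3)$vertices
  skull <- dirs * 80
  face <- cf_mesh(dirs * 90, sph$faces)
  f <- measure_fstd(skull, dirs, face)
  expect_equal(unname(f$depths), rep(10, nrow(skull)), tolerance = 1e-6)
  # implied face points lie on the measured surface
  expect_lt(max(abs(row_norms(f$face_points) - 90)), 1e-6)

  # uniform 5 mm offset along arbitrary directions
  set.seed(20)
  sub <- skull[seq(1, nrow(skull), by = 13), ]
  d2 <- normalize_rows(sub)
  off <- cf_mesh(skull + dirs * 5, sph$faces)
  f2 <- measure_fstd(sub, d2, off)
  expect_equal(unname(f2$depths), rep(5, nrow(sub)), tolerance = 1e-3)

  # rays pointing away from the surface are flagged missing
  f3 <- measure_fstd(matrix(c(0, 0, 200), 1, 3), matrix(c(0, 0, 1), 1, 3),
                     face)
  expect_true(is.na(f3$depths[1]))
  expect_error(measure_fstd(skull, dirs, cf_mesh(diag(3),
                                                 matrix(integer(0), 0, 3))),
               "empty")
})

test_that("FSTD statistics use sample SD and handle missingness", {
  sph <- sphere_mesh(2)
  dirs <- icosphere(2)$vertices
  skull <- dirs * 80
  mk <- function(r) measure_fstd(skull, dirs, cf_mesh(dirs * r, sph$faces))
  same <- list(mk(90), mk(90), mk(90))
  st <- fstd_statistics(same)
  expect_lt(max(st$sd), 1e-9)
  st2 <- fstd_statistics(list(mk(88), mk(90)))
  expect_equal(unname(st2$mean[1]), 9, tolerance = 1e-5)
  expect_equal(unname(st2$sd[1]), sqrt(2), tolerance = 1e-5)  # ddof = 1
  expect_equal(st2$cohort_mean, 9, tolerance = 1e-5)

  # generator-truth recovery: per-point means within CLT bound
  co <- std_cohort()
  model_dirs <- normalize_rows(icosphere(3)$vertices)
  fields <- lapply(seq_along(co$skulls), function(i)
    measure_fstd(co$skulls[[i]]$vertices, model_dirs, co$faces[[i]]))
  st3 <- fstd_statistics(fields)
  true_mean <- colMeans(co$truth$depth_fields)
  err <- abs(st3$mean - true_mean)
  n <- length(co$skulls)
  bound <- 3 * pmax(apply(co$truth$depth_fields, 2, stats::sd), 0.2) / sqrt(n)
  expect_gt(mean(err < bound + 0.2), 0.9)
})

test_that("envelope building is the Eq-1 inverse of measurement", {
  co <- std_cohort()
  dirs <- normalize_rows(icosphere(3)$vertices)
  skull <- co$skulls[[1]]$vertices
  f <- measure_fstd(skull, dirs, co$faces[[1]])
  env <- build_envelope(skull, dirs, f$depths, faces = co$template_faces)
  cp <- project_semilandmarks(env$points$points, co$faces[[1]])
  expect_lt(max(attr(cp, "distance")), 1e-6)

  env0 <- build_envelope(skull, dirs, rep(0, nrow(skull)),
                         faces = co$template_faces)
  expect_identical(env0$points$points, skull)

  # missing depths are imputed from neighbours
  d <- f$depths
  d[c(3, 50)] <- NA
  envi <- build_envelope(skull, dirs, d, faces = co$template_faces)
  expect_identical(envi$imputed, c(3L, 50L))
  nb <- order(row_norms(sweep(skull, 2, skull[3, ])))[2:9]
  expect_lt(abs(envi$depths[3] - mean(f$depths[nb])), 1)
  expect_error(build_envelope(skull, dirs, rep(NA_real_, nrow(skull))),
               "all depths missing")
})

test_that("organ ridge regression recovers exact linear maps", {
  set.seed(22)
  X <- matrix(stats::rnorm(40 * 4), 40)
  L <- matrix(stats::rnorm(12), 3, 4)
  Y <- X %*% t(L)
  M <- fit_organ_regression(X, Y, eta = 0)
  expect_lt(max(abs(M - L)), 1e-8)
  # eta -> infinity: map collapses to zero (mean-shape prediction)
  expect_lt(max(abs(fit_organ_regression(X, Y, eta = 1e6))), 1e-6)
  # ridge path: predicted score norm non-increasing in eta
  x0 <- X[1, ]
  norms <- vapply(c(0, 0.1, 1, 10, 100), function(e)
    sqrt(sum((fit_organ_regression(X, Y, e) %*% x0)^2)), 0)
  expect_false(is.unsorted(-norms))
  # singular OLS advises ridge
  Xs <- cbind(X[, 1], X[, 1], X[, 2:4])
  expect_error(fit_organ_regression(Xs, Y, eta = 0), "eta > 0")
})

test_that("organ model prediction is exact on a noiseless linear cohort", {
  # soft configurations are an exact linear function of shared latents
  set.seed(23)
  hard_base <- matrix(stats::rnorm(30), 10) * 5
  hard_mode <- list(matrix(stats::rnorm(30), 10), matrix(stats::rnorm(30), 10))
  soft_base <- matrix(stats::rnorm(24), 8) * 4
  soft_mode <- list(matrix(stats::rnorm(24), 8), matrix(stats::rnorm(24), 8))
  zs <- lapply(1:12, function(i) stats::rnorm(2) * c(0.2, 0.1))
  hard <- lapply(zs, function(z)
    hard_base + z[1] * hard_mode[[1]] + z[2] * hard_mode[[2]])
  soft <- lapply(zs, function(z)
    soft_base + z[1] * soft_mode[[1]] + z[2] * soft_mode[[2]])
  # form coordinates (no unit-size scaling) keep the cohort exactly linear
  model <- fit_organ_model(hard, soft, eta = 0, cumulative_threshold = 1,
                           with_scaling = FALSE)
  for (i in c(1, 5)) {
    pred <- predict_organ(model, hard[[i]])
    expect_lt(procrustes_distance(pred, soft[[i]], with_scaling = FALSE),
              1e-6)
  }
  # hard mean -> soft mean
  pred_mean <- predict_organ(model, model$hard_space$mean)
  expect_lt(procrustes_distance(pred_mean, model$soft_space$mean,
                                with_scaling = FALSE), 1e-6)
  # zeroed map -> soft mean for any input
  model0 <- model; model0$M[] <- 0
  expect_lt(procrustes_distance(predict_organ(model0, hard[[3]]),
                                model$soft_space$mean), 1e-12)
  expect_error(predict_organ(model, hard[[1]][1:5, ]), "expects")

  # held-out alignment rotations are the only (second-order) error source
  lo <- organ_loocv(hard, soft, eta = 0, cumulative_threshold = 1,
                    with_scaling = FALSE)
  expect_lt(lo$mean, 5e-3)
  expect_lt(lo$max_ratio, 0.05)
})

test_that("noisy-cohort organ prediction beats the mean-shape baseline", {
  # a strongly coupled organ world (high SNR), n = 20
  co <- cached_cohort("organ_snr",
                      cohort_spec(n = 20, seed = 1, subdivisions = 3,
                                  organ_rho = 0.9, organ_noise_sd = 0.1,
                                  subject_depth_sd = 0.2,
                                  depth_noise_sd = 0.1))
  nasal <- which(co$skull_labels$labels == "nasal")
  nose <- which(co$face_labels$labels == "nose")
  hard <- lapply(co$skulls, function(m) m$vertices[nasal, ])
  soft <- lapply(co$faces, function(m) m$vertices[nose, ])
  lo <- organ_loocv(hard, soft, eta = NULL)  # eta by LOOCV grid
  # baseline predictor (the mean shape) has ratio 1 by construction
  expect_lt(mean(lo$ratios), 1)
  expect_gte(mean(lo$ratios < 1), 0.9)
})

test_that("denser configurations do not hurt organ prediction", {
  wins <- 0
  n_seeds <- 8
  for (seed in seq_len(n_seeds)) {
    co <- cached_cohort(paste0("organ", seed),
                        cohort_spec(n = 16, seed = 200 + seed,
                                    subdivisions = 3, organ_rho = 0.9,
                                    organ_noise_sd = 0.1,
                                    subject_depth_sd = 0.2,
                                    depth_noise_sd = 0.1))
    nasal <- which(co$skull_labels$labels == "nasal")
    nose <- which(co$face_labels$labels == "nose")
    hard_dense <- lapply(co$skulls, function(m) m$vertices[nasal, ])
    soft <- lapply(co$faces, function(m) m$vertices[nose, ])
    sparse_idx <- nasal[seq(1, length(nasal), length.out = 5)]
    hard_sparse <- lapply(co$skulls, function(m) m$vertices[sparse_idx, ])
    dense <- organ_loocv(hard_dense, soft, eta = 0.1)
    sparse <- organ_loocv(hard_sparse, soft, eta = 0.1)
    if (dense$mean <= sparse$mean) wins <- wins + 1
  }
  expect_gte(wins / n_seeds, 0.7)
})
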
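# mesh/landmark I/O, normals, sampling, reconstruction, alignment, loops

test_that("OBJ and PLY round-trips preserve geometry", {
  obj <- unit_cube_obj(withr::local_tempfile(fileext = ".obj"))
  m <- read_mesh(obj)
  expect_equal(nrow(m$vertices), 8)
  expect_equal(nrow(m$faces), 12)

  obj2 <- withr::local_tempfile(fileext = ".obj")
  write_mesh(m, obj2)
  m2 <- read_mesh(obj2)
  expect_lt(max(abs(m2$vertices - m$vertices)), 1e-4)

  sph <- sphere_mesh(2, 80)
  for (binary in c(TRUE, FALSE)) {
    ply <- withr::local_tempfile(fileext = ".ply")
    write_mesh(sph, ply, binary = binary)
    s2 <- read_mesh(ply)
    expect_lt(max(abs(s2$vertices - sph$vertices)), 1e-6)
    expect_identical(s2$faces, sph$faces)
  }
})

test_that("malformed mesh files raise parse errors naming the problem", {
  bad <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1 2 9"), bad)
  expect_error(read_mesh(bad), "face index 9")
  expect_error(cf_mesh(diag(3), matrix(c(1, 1, 2), 1)), "repeats a vertex")
  expect_error(read_mesh(withr::local_tempfile(fileext = ".xyz")))
})

test_that("facial landmark CSV reading validates the 52-name scheme", {
  scheme <- facial_landmark_scheme()
  expect_length(scheme, 52)
  expect_equal(sum(!grepl("\\((L|R)\\)$", scheme)), 8)   # median landmarks
  expect_equal(sum(grepl("\\((L|R)\\)$", scheme)), 44)   # bilateral

  csv <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(name = scheme, x = stats::rnorm(52), y = stats::rnorm(52),
                   z = stats::rnorm(52))
  utils::write.csv(df, csv, row.names = FALSE)
  lm <- read_landmarks(csv, scheme = scheme, strict = TRUE)
  expect_identical(lm$names, scheme)

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("name,x,y,z", empty)
  expect_error(read_landmarks(empty), "empty")

  dup <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(rbind(df, df[44, ]), dup, row.names = FALSE)
  expect_error(read_landmarks(dup), "duplicate")

  unk <- withr::local_tempfile(fileext = ".csv")
  df$name[1] <- "Unknown point"
  utils::write.csv(df, unk, row.names = FALSE)
  expect_error(read_landmarks(unk, scheme = scheme, strict = TRUE),
               "Unknown point")
})

test_that("vertex normals are outward, unit, and near-analytic on a sphere", {
  m <- compute_vertex_normals(sphere_mesh(3, 80))
  expect_lt(max(abs(row_norms_t(m$normals) - 1)), 1e-6)
  ang <- acos(pmin(1, rowSums(m$normals * m$vertices / 80)))
  expect_lt(max(ang) * 180 / pi, 2)

  # planar patch: all normals identical up to global sign
  d <- disk_mesh()
  dn <- compute_vertex_normals(d)
  expect_lt(max(abs(abs(dn$normals[, 3]) - 1)), 1e-9)
  expect_equal(length(unique(sign(dn$normals[, 3]))), 1)

  # flipped faces get re-unified outward
  flipped <- sphere_mesh(2, 80)
  idx <- seq(1, nrow(flipped$faces), by = 2)
  flipped$faces[idx, ] <- flipped$faces[idx, c(1, 3, 2)]
  fn <- compute_vertex_normals(flipped)
  ctr <- colMeans(fn$vertices)
  expect_true(all(rowSums(fn$normals * sweep(fn$vertices, 2, ctr)) > 0))
})

test_that("poisson-disk sampling hits target counts with blue-noise spacing", {
  m <- sphere_mesh(3, 80)
  for (nt in c(215, 556)) {
    cfg <- poisson_disk_sample(m, nt, seed = 7)
    expect_lte(abs(nrow(cfg$points) - nt), 0.02 * nt + 1)
    r <- attr(cfg, "radius")
    d <- as.matrix(stats::dist(cfg$points))
    diag(d) <- Inf
    expect_gte(min(d), 0.5 * r)
  }
  # determinism
  a <- poisson_disk_sample(m, 300, seed = 3)
  b <- poisson_disk_sample(m, 300, seed = 3)
  expect_identical(a$points, b$points)
})

test_that("minimum-spacing property holds across seeded runs", {
  m <- sphere_mesh(2, 40)
  for (seed in 1:20) {
    cfg <- poisson_disk_sample(m, 120, seed = seed)
    d <- as.matrix(stats::dist(cfg$points))
    diag(d) <- Inf
    expect_gte(min(d), 0.5 * attr(cfg, "radius"))
  }
})

test_that("surface reconstruction keeps points fixed and respects radii", {
  set.seed(21)
  # dense exact-sphere samples
  p <- matrix(stats::rnorm(3 * 1500), ncol = 3)
  p <- 80 * p / row_norms_t(p)
  rec <- reconstruct_surface(p)
  expect_lt(max(abs(row_norms_t(rec$vertices) - 80)), 1e-9)
  expect_gte(length(unique(as.vector(rec$faces))) / nrow(p), 0.95)
  # faces only connect nearby points
  rmax <- max(attr(rec, "radii") %||% c(4 * 80 * sqrt(4 * pi / 1500)))
  el <- row_norms_t(rec$vertices[rec$faces[, 1], ] -
                      rec$vertices[rec$faces[, 2], ])
  expect_lt(max(el), 80)  # far smaller than the sphere diameter

  expect_error(reconstruct_surface(p[1:3, ]), "at least 4")
  expect_error(reconstruct_surface(cbind(1:10, 0, 0)), "collinear")

  gr <- as.matrix(expand.grid(x = 0:8, y = 0:8))
  pl <- cbind(gr, 0)
  rp <- reconstruct_surface(pl)
  fn <- face_normals_t(rp)
  expect_true(all(abs(fn[, 3]) / row_norms_t(fn) > 1 - 1e-9))
})

test_that("frankfort alignment recovers known motions and is an isometry", {
  co <- std_cohort()
  skull <- co$skulls[[1]]
  lm <- co$skull_landmarks[[1]]
  gl <- function(nm) lm$points[match(nm, lm$names), ]
  fa <- frankfort_align(skull, gl("Lp"), gl("Rp"), gl("Lo"), gl("G"))
  # defining properties of the frame
  expect_lt(max(abs((fa$transform(rbind(gl("Lp"), gl("Rp")))[, 2:3]))), 1e-9)
  expect_lt(abs(fa$transform(rbind(gl("Lo")))[1, 3]), 1e-9)
  expect_gt(fa$transform(rbind(gl("G")))[1, 2], 0)
  expect_equal(det(fa$R), 1, tolerance = 1e-12)
  # isometry: pairwise distances preserved
  idx <- seq(1, nrow(skull$vertices), by = 37)
  d0 <- stats::dist(skull$vertices[idx, ])
  d1 <- stats::dist(fa$mesh$vertices[idx, ])
  expect_lt(max(abs(d0 - d1)), 1e-9)

  # already canonical: applying twice is the identity
  lm2 <- cf_landmarks(lm$names, fa$transform(lm$points))
  gl2 <- function(nm) lm2$points[match(nm, lm2$names), ]
  fa2 <- frankfort_align(fa$mesh, gl2("Lp"), gl2("Rp"), gl2("Lo"), gl2("G"))
  expect_lt(max(abs(fa2$mesh$vertices - fa$mesh$vertices)), 1e-9)

  # known rigid motion is undone exactly
  R <- rot_x(0.6) %*% rot_z(-0.3)
  t <- c(5, -2, 9)
  moved <- skull
  moved$vertices <- skull$vertices %*% t(R) + matrix(t, nrow(skull$vertices),
                                                     3, byrow = TRUE)
  mlm <- lm$points %*% t(R) + matrix(t, nrow(lm$points), 3, byrow = TRUE)
  fam <- frankfort_align(moved, mlm[1, ], mlm[2, ], mlm[3, ], mlm[4, ])
  expect_lt(max(abs(fam$mesh$vertices - fa$mesh$vertices)), 1e-9)

  expect_error(frankfort_align(skull, gl("Lp"), gl("Lp"), gl("Lo"), gl("G")),
               "porions")
  expect_error(frankfort_align(skull, c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                               gl("G")), "collinear")
})

test_that("boundary loop extraction follows component topology", {
  d <- disk_mesh()
  expect_length(extract_boundary_loops(d), 1)

  # annulus: remove faces touching the centre vertex
  ann <- d
  keep <- rowSums(matrix(ann$faces %in% 1L, ncol = 3)) == 0
  ann$faces <- ann$faces[keep, , drop = FALSE]
  expect_length(extract_boundary_loops(ann), 2)

  expect_length(extract_boundary_loops(sphere_mesh(2)), 0)

  co <- std_cohort()
  expect_length(extract_boundary_loops(co$faces[[1]], co$face_labels,
                                       "nose"), 1)
})

test_that("component submesh bookkeeping covers and partitions vertices", {
  co <- std_cohort()
  expect_error(cf_labels(c("envelope", "mystery")), "mystery")
  sub <- component_submesh(co$skulls[[1]], co$skull_labels, "nasal")
  expect_true(all(co$skull_labels$labels[sub$vertex_index] == "nasal"))
  expect_error(component_submesh(co$skulls[[1]], co$skull_labels, "nose"),
               "not present")
})
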
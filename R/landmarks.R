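#' Facial landmark scheme (52 anatomical landmarks)
#'
#' The standard anthropometric facial scheme used by the package: 8 median
#' landmarks and 22 bilateral pairs (44 points), ordered with bilateral names
#' carrying explicit `(L)`/`(R)` suffixes.
#'
#' @return character vector of 52 landmark names.
#' @export
facial_landmark_scheme <- function() {
  bilat <- function(nm) paste0(nm, c(" (L)", " (R)"))
  c(bilat("Medial canthus"), bilat("Lateral canthus"),
    "Nasal bridge", "Middle of nose", "Tip of nose", "Subnasale",
    bilat("External alar curvature"), bilat("Superior alar curvature"),
    bilat("Alare"), bilat("Alar curvature point"),
    bilat("Corner of mouth"), bilat("Crista philtra"),
    "Middle of cupid's bow upper lip", "Middle of oral fissure",
    "Middle of bottom lip", "Tip of chin",
    bilat("Otobasion superius"), bilat("Superior auricle"),
    bilat("Posterior auricle"), bilat("Inferior auricle"),
    bilat("Anterior cymba concha"), bilat("Superior cymba concha"),
    bilat("Posterior concha"), bilat("Intertragic incisure"),
    bilat("Incisura intertragica"), bilat("Tragion"),
    bilat("Medial concha"), bilat("Superior cavum concha"),
    bilat("Otobasion posterius"), bilat("Otobasion inferius"))
}

#' Ordered named landmark set
#'
#' @param names character vector of unique landmark names.
#' @param points `k x 3` matrix of coordinates in mm.
#' @return An object of class `cf_landmarks`.
#' @export
cf_landmarks <- function(names, points) {
  points <- as_pts(points)
  names <- as.character(names)
  if (length(names) != nrow(points))
    stop("one name per landmark row required")
  dup <- names[duplicated(names)]
  if (length(dup) > 0)
    stop("duplicate landmark name(s): ", paste(unique(dup), collapse = ", "))
  structure(list(names = names, points = points), class = "cf_landmarks")
}

#' @export
print.cf_landmarks <- function(x, ...) {
  cat(sprintf("<cf_landmarks> %d landmarks\n", length(x$names)))
  invisible(x)
}

#' Read landmarks from a CSV file
#'
#' Expects a UTF-8 CSV with header `name,x,y,z` (decimal point, no thousands
#' separators). Row order is preserved.
#'
#' @param path CSV path.
#' @param scheme optional character vector of allowed names; when given with
#'   `strict = TRUE`, unknown names raise an error.
#' @param strict validate names against `scheme`.
#' @return A [cf_landmarks()].
#' @export
read_landmarks <- function(path, scheme = NULL, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (nrow(df) == 0) stop("empty landmark file: ", path)
  req <- c("name", "x", "y", "z")
  if (!all(req %in% names(df)))
    stop("landmark CSV must have header name,x,y,z")
  lm <- cf_landmarks(df$name, cbind(df$x, df$y, df$z))
  if (!is.null(scheme) && strict) {
    unknown <- setdiff(lm$names, scheme)
    if (length(unknown) > 0)
      stop("unknown landmark name(s): ", paste(unknown, collapse = ", "))
  }
  lm
}

#' Write landmarks to CSV
#' @param lm a [cf_landmarks()].
#' @param path output path.
#' @export
write_landmarks <- function(lm, path) {
  df <- data.frame(name = lm$names, x = lm$points[, 1], y = lm$points[, 2],
                   z = lm$points[, 3])
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Landmark + semilandmark configuration
#'
#' A `k x 3` ordered point matrix in fixed correspondence across specimens;
#' named landmarks precede semilandmarks.
#'
#' @param points `k x 3` matrix (mm).
#' @param n_landmarks how many leading rows are named landmarks.
#' @param landmark_names optional names for the leading rows.
#' @return object of class `cf_config`.
#' @export
cf_config <- function(points, n_landmarks = 0L, landmark_names = NULL) {
  points <- as_pts(points)
  n_landmarks <- as.integer(n_landmarks)
  if (n_landmarks < 0 || n_landmarks > nrow(points))
    stop("n_landmarks out of range")
  if (!is.null(landmark_names) && length(landmark_names) != n_landmarks)
    stop("landmark_names must have length n_landmarks")
  structure(list(points = points, n_landmarks = n_landmarks,
                 n_semilandmarks = nrow(points) - n_landmarks,
                 landmark_names = landmark_names), class = "cf_config")
}

#' @export
print.cf_config <- function(x, ...) {
  cat(sprintf("<cf_config> %d points (%d landmarks + %d semilandmarks)\n",
              nrow(x$points), x$n_landmarks, x$n_semilandmarks))
  invisible(x)
}

config_points <- function(x) {
  if (inherits(x, "cf_config")) x$points
  else if (inherits(x, "cf_landmarks")) x$points
  else as_pts(x)
}

#' Per-vertex component labels
#'
#' Partitions a template mesh's vertices into named components (e.g.
#' `envelope`, `nasal`, `oral` for skulls; `envelope`, `nose`, `mouth` for
#' faces), with `excluded` allowed.
#'
#' @param labels character vector, one label per vertex.
#' @param components allowed label vocabulary.
#' @return object of class `cf_labels`.
#' @export
cf_labels <- function(labels,
                      components = c("envelope", "nasal", "oral", "nose",
                                     "mouth", "excluded")) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), components)
  if (length(bad) > 0)
    stop("unknown component label(s): ", paste(bad, collapse = ", "))
  structure(list(labels = labels, components = components),
            class = "cf_labels")
}

#' Read component labels from CSV (`vertex_index,label`; 1-based indices)
#' @param path CSV path.
#' @param n_vertices expected vertex count.
#' @export
read_labels <- function(path, n_vertices) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("vertex_index", "label") %in% names(df)))
    stop("label CSV must have header vertex_index,label")
  labels <- rep("excluded", n_vertices)
  if (any(df$vertex_index < 1 | df$vertex_index > n_vertices))
    stop("vertex_index out of range")
  labels[df$vertex_index] <- df$label
  cf_labels(labels)
}

#' Extract the submesh of one labelled component
#'
#' Keeps faces whose three vertices all carry the component's label.
#'
#' @param mesh a [cf_mesh()].
#' @param labels a [cf_labels()] over the mesh vertices.
#' @param component component name.
#' @return list with `mesh` (reindexed submesh) and `vertex_index` (original
#'   1-based indices of its vertices).
#' @export
component_submesh <- function(mesh, labels, component) {
  if (!component %in% labels$labels)
    stop("component '", component, "' not present in labels")
  keep_v <- which(labels$labels == component)
  inset <- logical(nrow(mesh$vertices))
  inset[keep_v] <- TRUE
  fkeep <- inset[mesh$faces[, 1]] & inset[mesh$faces[, 2]] &
    inset[mesh$faces[, 3]]
  f <- mesh$faces[fkeep, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  sub <- cf_mesh(mesh$vertices[used, , drop = FALSE],
                 matrix(remap[f], ncol = 3))
  list(mesh = sub, vertex_index = used)
}

#' Align a mesh to the Frankfort coordinate system
#'
#' Places the origin at the midpoint of the two porions, the x-axis along
#' right-to-left porion, the plane through both porions and the left orbitale
#' at z = 0, and orients the frame so the glabella has positive y (anterior).
#' The transform is rigid (rotation + translation, no scaling).
#'
#' @param mesh a [cf_mesh()] (or NULL to transform landmarks only).
#' @param Lp,Rp,Lo,G 3-vectors: left/right porion, left orbitale, glabella.
#' @return list with `mesh` (aligned), `R` (3x3 rotation), `t` (translation)
#'   such that aligned = (x + t) %*% t(R) ... specifically
#'   `aligned_points = sweep(points, 2, -t) %*% R` with `R` orthonormal.
#' @export
frankfort_align <- function(mesh, Lp, Rp, Lo, G) {
  Lp <- as.numeric(Lp); Rp <- as.numeric(Rp)
  Lo <- as.numeric(Lo); G <- as.numeric(G)
  if (!all(is.finite(c(Lp, Rp, Lo, G)))) stop("non-finite landmark")
  origin <- (Lp + Rp) / 2
  xaxis <- Lp - Rp
  nx <- sqrt(sum(xaxis^2))
  if (nx < 1e-9) stop("degenerate frame: porions coincide")
  xaxis <- xaxis / nx
  w <- Lo - origin
  w_perp <- w - sum(w * xaxis) * xaxis
  if (sqrt(sum(w_perp^2)) < 1e-9)
    stop("degenerate frame: Lp, Rp, Lo are collinear")
  # z axis normal to the Frankfort plane (through Lp, Rp, Lo)
  zaxis <- c(xaxis[2] * w_perp[3] - xaxis[3] * w_perp[2],
             xaxis[3] * w_perp[1] - xaxis[1] * w_perp[3],
             xaxis[1] * w_perp[2] - xaxis[2] * w_perp[1])
  zaxis <- zaxis / sqrt(sum(zaxis^2))
  yaxis <- c(zaxis[2] * xaxis[3] - zaxis[3] * xaxis[2],
             zaxis[3] * xaxis[1] - zaxis[1] * xaxis[3],
             zaxis[1] * xaxis[2] - zaxis[2] * xaxis[1])
  # glabella anterior: positive y
  if (sum((G - origin) * yaxis) < 0) {
    yaxis <- -yaxis
    zaxis <- -zaxis
  }
  Rmat <- cbind(xaxis, yaxis, zaxis)  # columns are new axes in old frame
  transform <- function(p) sweep(as_pts(p), 2, origin) %*% Rmat
  out_mesh <- mesh
  if (!is.null(mesh)) {
    out_mesh$vertices <- transform(mesh$vertices)
    if (!is.null(mesh$normals)) out_mesh$normals <- mesh$normals %*% Rmat
  }
  list(mesh = out_mesh, R = Rmat, origin = origin, transform = transform)
}

#' Extract ordered closed boundary loops of a labelled component
#'
#' Boundary edges are edges of the component's submesh incident to exactly
#' one face. Each loop is returned as an ordered, closed cycle of original
#' vertex indices with consistent winding (following face orientation).
#'
#' @param mesh a [cf_mesh()].
#' @param labels a [cf_labels()]; pass `NULL` to use the whole mesh.
#' @param component component name (ignored when `labels` is NULL).
#' @return list of integer vectors (vertex indices into `mesh$vertices`);
#'   empty list when the submesh is closed.
#' @export
extract_boundary_loops <- function(mesh, labels = NULL, component = NULL) {
  if (!is.null(labels)) {
    sub <- component_submesh(mesh, labels, component)
    f <- sub$mesh$faces
    vmap <- sub$vertex_index
  } else {
    f <- mesh$faces
    vmap <- seq_len(nrow(mesh$vertices))
  }
  if (nrow(f) == 0) return(list())
  # directed edges; boundary edge = undirected edge with exactly one face
  de <- rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]),
              cbind(f[, 3], f[, 1]))
  key <- paste(pmin(de[, 1], de[, 2]), pmax(de[, 1], de[, 2]))
  cnt <- table(key)
  bnd <- de[cnt[key] == 1, , drop = FALSE]
  if (nrow(bnd) == 0) return(list())
  nxt <- new.env(hash = TRUE)
  for (i in seq_len(nrow(bnd)))
    assign(as.character(bnd[i, 1]), bnd[i, 2], envir = nxt)
  remaining <- new.env(hash = TRUE)
  for (i in seq_len(nrow(bnd)))
    assign(as.character(bnd[i, 1]), TRUE, envir = remaining)
  loops <- list()
  for (i in seq_len(nrow(bnd))) {
    start <- bnd[i, 1]
    if (!exists(as.character(start), envir = remaining)) next
    loop <- integer(0)
    cur <- start
    repeat {
      if (!exists(as.character(cur), envir = remaining)) break
      loop <- c(loop, cur)
      rm(list = as.character(cur), envir = remaining)
      cur <- get(as.character(cur), envir = nxt)
      if (cur == start) break
    }
    if (length(loop) >= 3) loops[[length(loops) + 1]] <- vmap[loop]
  }
  loops
}
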
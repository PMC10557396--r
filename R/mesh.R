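#' Triangle surface mesh
#'
#' Constructs a triangle mesh from an `n x 3` vertex matrix (millimetres) and
#' an `m x 3` matrix of 1-based vertex-index triples. Per-vertex unit normals
#' are optional and can be (re)computed with [compute_vertex_normals()].
#'
#' @param vertices numeric `n x 3` matrix of vertex coordinates in mm.
#' @param faces integer `m x 3` matrix of 1-based vertex indices.
#' @param normals optional numeric `n x 3` matrix of unit vertex normals.
#' @return An object of class `cf_mesh` with elements `vertices`, `faces`,
#'   and optionally `normals`.
#' @export
cf_mesh <- function(vertices, faces, normals = NULL) {
  vertices <- as_pts(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(faces) != 3) stop("faces must be an m x 3 index matrix")
  if (nrow(faces) > 0) {
    if (min(faces) < 1 || max(faces) > nrow(vertices))
      stop("face index out of range: vertex indices must be in 1..",
           nrow(vertices))
    if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
            faces[, 2] == faces[, 3]))
      stop("degenerate face: a face repeats a vertex")
  }
  if (!is.null(normals)) {
    normals <- as_pts(normals)
    if (nrow(normals) != nrow(vertices))
      stop("normals must have one row per vertex")
  }
  structure(list(vertices = vertices, faces = faces, normals = normals),
            class = "cf_mesh")
}

#' @export
print.cf_mesh <- function(x, ...) {
  cat(sprintf("<cf_mesh> %d vertices, %d faces%s\n", nrow(x$vertices),
              nrow(x$faces),
              if (!is.null(x$normals)) ", with normals" else ""))
  invisible(x)
}

#' Read a triangle mesh from PLY or OBJ
#'
#' Supports ASCII and binary little-endian PLY (vertex x/y/z with optional
#' nx/ny/nz, face vertex index lists) and OBJ `v`/`f` records. Units are
#' assumed to be millimetres.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"ply"` or `"obj"`.
#' @return A [cf_mesh()].
#' @export
read_mesh <- function(path, format = c("auto", "ply", "obj")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, ply = "ply", obj = "obj",
                     stop("cannot infer mesh format from extension '", ext, "'"))
  }
  if (format == "ply") read_ply(path) else read_obj(path)
}

#' Write a triangle mesh to PLY or OBJ
#'
#' @param mesh a [cf_mesh()].
#' @param path output path.
#' @param format `"auto"`, `"ply"` or `"obj"`.
#' @param binary for PLY, write binary little-endian (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "ply", "obj"),
                       binary = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, ply = "ply", obj = "obj",
                     stop("cannot infer mesh format from extension '", ext, "'"))
  }
  if (format == "ply") write_ply(mesh, path, binary = binary)
  else write_obj(mesh, path)
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  if (length(vlines) == 0) stop("OBJ parse error: no vertex ('v') records")
  vparts <- strsplit(sub("^v\\s+", "", vlines), "\\s+")
  if (any(lengths(vparts) < 3))
    stop("OBJ parse error: vertex record with fewer than 3 coordinates")
  verts <- t(vapply(vparts, function(p) as.numeric(p[1:3]), numeric(3)))
  if (anyNA(verts)) stop("OBJ parse error: non-numeric vertex coordinate")
  faces <- matrix(integer(0), 0, 3)
  if (length(flines) > 0) {
    fparts <- strsplit(sub("^f\\s+", "", flines), "\\s+")
    parse_face <- function(p) {
      idx <- as.integer(vapply(p, function(tok) strsplit(tok, "/")[[1]][1], ""))
      if (anyNA(idx)) stop("OBJ parse error: non-integer face index")
      idx
    }
    tri <- lapply(fparts, function(p) {
      idx <- parse_face(p)
      if (length(idx) < 3) stop("OBJ parse error: face with < 3 vertices")
      # fan-triangulate polygons
      cbind(idx[1], idx[2:(length(idx) - 1)], idx[3:length(idx)])
    })
    faces <- do.call(rbind, tri)
  }
  if (nrow(faces) > 0 && max(faces) > nrow(verts))
    stop("OBJ parse error: face index ", max(faces), " exceeds vertex count ",
         nrow(verts))
  cf_mesh(verts, faces)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.8f %.8f %.8f", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  if (nrow(mesh$faces) > 0)
    writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                       mesh$faces[, 3]), con)
  invisible(path)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_hline <- function() {
    chars <- raw(0)
    repeat {
      b <- readBin(con, "raw", 1)
      if (length(b) == 0) stop("PLY parse error: truncated header")
      if (b == as.raw(10)) break
      chars <- c(chars, b)
    }
    trimws(rawToChar(chars))
  }
  if (read_hline() != "ply") stop("PLY parse error: missing 'ply' magic")
  fmt <- NULL
  elements <- list()  # name -> list(count, props = data.frame(type, name, list))
  cur <- NULL
  repeat {
    ln <- read_hline()
    if (ln == "end_header") break
    tok <- strsplit(ln, "\\s+")[[1]]
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (tok[2] == "list")
        cur$props[[length(cur$props) + 1]] <-
          list(list = TRUE, count_type = tok[3], type = tok[4], name = tok[5])
      else
        cur$props[[length(cur$props) + 1]] <-
          list(list = FALSE, type = tok[2], name = tok[3])
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(fmt)) stop("PLY parse error: no format line")
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("PLY parse error: unsupported format '", fmt, "'")
  type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                 short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                 int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                 float = 4L, float32 = 4L, double = 8L, float64 = 8L)
  read_scalar_bin <- function(type, n = 1L) {
    sz <- type_size[[type]]
    if (type %in% c("float", "float32", "double", "float64"))
      readBin(con, "double", n, size = sz, endian = "little")
    else
      readBin(con, "integer", n, size = sz, endian = "little",
              signed = !(sz < 4 && grepl("^u", type)))
  }
  verts <- NULL; norms <- NULL; faces <- NULL
  if (fmt == "ascii") {
    rest <- readLines(con, warn = FALSE)
    pos <- 1L
    for (el in elements) {
      pnames <- vapply(el$props, `[[`, "", "name")
      if (el$name == "vertex") {
        rows <- rest[pos:(pos + el$count - 1L)]; pos <- pos + el$count
        m <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
        if (anyNA(m)) stop("PLY parse error: non-numeric vertex data")
        verts <- m[, match(c("x", "y", "z"), pnames), drop = FALSE]
        if (all(c("nx", "ny", "nz") %in% pnames))
          norms <- m[, match(c("nx", "ny", "nz"), pnames), drop = FALSE]
      } else if (el$name == "face") {
        rows <- rest[pos:(pos + el$count - 1L)]; pos <- pos + el$count
        tri <- lapply(strsplit(trimws(rows), "\\s+"), function(p) {
          k <- as.integer(p[1])
          idx <- as.integer(p[2:(1 + k)])
          cbind(idx[1], idx[2:(k - 1)], idx[3:k])
        })
        faces <- do.call(rbind, tri) + 1L
      } else pos <- pos + el$count
    }
  } else {
    for (el in elements) {
      pnames <- vapply(el$props, `[[`, "", "name")
      if (el$name == "vertex") {
        islist <- vapply(el$props, `[[`, TRUE, "list")
        if (any(islist)) stop("PLY parse error: list property on vertex")
        m <- matrix(0, el$count, length(el$props))
        for (i in seq_len(el$count))
          for (j in seq_along(el$props))
            m[i, j] <- read_scalar_bin(el$props[[j]]$type)
        verts <- m[, match(c("x", "y", "z"), pnames), drop = FALSE]
        if (all(c("nx", "ny", "nz") %in% pnames))
          norms <- m[, match(c("nx", "ny", "nz"), pnames), drop = FALSE]
      } else if (el$name == "face") {
        tri <- vector("list", el$count)
        for (i in seq_len(el$count)) {
          for (j in seq_along(el$props)) {
            p <- el$props[[j]]
            if (p$list) {
              k <- read_scalar_bin(p$count_type)
              idx <- read_scalar_bin(p$type, k)
              if (p$name %in% c("vertex_indices", "vertex_index"))
                tri[[i]] <- cbind(idx[1], idx[2:(k - 1)], idx[3:k])
            } else read_scalar_bin(p$type)
          }
        }
        faces <- do.call(rbind, tri) + 1L
      } else {
        for (i in seq_len(el$count))
          for (j in seq_along(el$props)) {
            p <- el$props[[j]]
            if (p$list) {
              k <- read_scalar_bin(p$count_type)
              read_scalar_bin(p$type, k)
            } else read_scalar_bin(p$type)
          }
      }
    }
  }
  if (is.null(verts)) stop("PLY parse error: no vertex element")
  if (is.null(faces)) faces <- matrix(integer(0), 0, 3)
  if (nrow(faces) > 0 && max(faces) > nrow(verts))
    stop("PLY parse error: face index ", max(faces) - 1L,
         " exceeds vertex count ", nrow(verts))
  cf_mesh(verts, faces, normals = norms)
}

write_ply <- function(mesh, path, binary = TRUE) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  has_n <- !is.null(mesh$normals)
  hdr <- c("ply",
           paste("format", if (binary) "binary_little_endian" else "ascii",
                 "1.0"),
           paste("element vertex", nv),
           "property double x", "property double y", "property double z")
  if (has_n) hdr <- c(hdr, "property double nx", "property double ny",
                      "property double nz")
  hdr <- c(hdr, paste("element face", nf),
           "property list uchar int vertex_indices", "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  vdata <- if (has_n) cbind(mesh$vertices, mesh$normals) else mesh$vertices
  if (binary) {
    writeBin(as.vector(t(vdata)), con, size = 8, endian = "little")
    if (nf > 0) {
      f0 <- mesh$faces - 1L
      for (i in seq_len(nf)) {
        writeBin(as.raw(3), con)
        writeBin(as.integer(f0[i, ]), con, size = 4, endian = "little")
      }
    }
  } else {
    txt <- apply(vdata, 1, function(r) paste(sprintf("%.10g", r),
                                             collapse = " "))
    writeBin(charToRaw(paste0(paste(txt, collapse = "\n"), "\n")), con)
    if (nf > 0) {
      f0 <- mesh$faces - 1L
      ftxt <- sprintf("3 %d %d %d", f0[, 1], f0[, 2], f0[, 3])
      writeBin(charToRaw(paste0(paste(ftxt, collapse = "\n"), "\n")), con)
    }
  }
  invisible(path)
}

face_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cross_rows(e1, e2)  # length = 2 * face area
}

#' Compute outward-oriented, area-weighted vertex normals
#'
#' Vertex normals are area-weighted averages of incident face normals. Face
#' winding is first made coherent by propagation across the edge-adjacency
#' graph; global outward orientation is then fixed by majority vote of
#' `normal . (v - centroid) > 0`.
#'
#' @param mesh a [cf_mesh()] with at least one face.
#' @return The mesh with a `normals` element (unit length) and coherently
#'   oriented faces.
#' @export
compute_vertex_normals <- function(mesh) {
  if (nrow(mesh$faces) < 1) stop("mesh has no faces")
  mesh <- orient_faces_coherently(mesh)
  fn <- face_normals(mesh)  # area-weighted by construction
  nv <- nrow(mesh$vertices)
  acc <- matrix(0, nv, 3)
  for (k in 1:3) {
    idx <- mesh$faces[, k]
    acc[, 1] <- acc[, 1] + tapply_add(fn[, 1], idx, nv)
    acc[, 2] <- acc[, 2] + tapply_add(fn[, 2], idx, nv)
    acc[, 3] <- acc[, 3] + tapply_add(fn[, 3], idx, nv)
  }
  lens <- row_norms(acc)
  isolated <- lens < 1e-12
  if (any(isolated)) {
    used <- unique(as.vector(mesh$faces))
    if (any(which(isolated) %in% used))
      stop("zero-area normal at a vertex incident to faces")
    acc[isolated, ] <- matrix(rep(c(0, 0, 1), sum(isolated)),
                              ncol = 3, byrow = TRUE)
    lens[isolated] <- 1
  }
  mesh$normals <- acc / lens
  mesh
}

tapply_add <- function(vals, idx, n) {
  out <- numeric(n)
  agg <- rowsum(vals, idx)
  out[as.integer(rownames(agg))] <- agg
  out
}

# Make face winding coherent across each connected component, then flip all
# faces if needed so normals point away from the centroid (majority vote).
orient_faces_coherently <- function(mesh) {
  f <- mesh$faces
  nf <- nrow(f)
  if (nf == 0) return(mesh)
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edges <- rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]),
                 cbind(f[, 3], f[, 1]))
  keys <- ekey(edges[, 1], edges[, 2])
  fidx <- rep(seq_len(nf), 3)
  by_edge <- split(fidx, keys)
  adj <- vector("list", nf)
  for (fs in by_edge) {
    if (length(fs) == 2) {
      adj[[fs[1]]] <- c(adj[[fs[1]]], fs[2])
      adj[[fs[2]]] <- c(adj[[fs[2]]], fs[1])
    }
  }
  visited <- logical(nf)
  flip <- logical(nf)
  directed <- function(fr) {
    a <- f[fr, ]
    if (flip[fr]) a <- rev(a)
    rbind(c(a[1], a[2]), c(a[2], a[3]), c(a[3], a[1]))
  }
  for (start in seq_len(nf)) {
    if (visited[start]) next
    queue <- start
    visited[start] <- TRUE
    while (length(queue) > 0) {
      cur <- queue[[1]]; queue <- queue[-1]
      de_cur <- directed(cur)
      for (nb in adj[[cur]]) {
        if (visited[nb]) next
        de_nb <- directed(nb)
        # shared edge must appear in opposite directions for coherence
        same_dir <- FALSE
        for (i in 1:3) for (j in 1:3)
          if (de_cur[i, 1] == de_nb[j, 1] && de_cur[i, 2] == de_nb[j, 2])
            same_dir <- TRUE
        if (same_dir) flip[nb] <- !flip[nb]
        visited[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
  }
  if (any(flip)) f[flip, ] <- f[flip, c(1, 3, 2)]
  mesh$faces <- f
  fn <- normalize_rows(cross_rows(
    mesh$vertices[f[, 2], , drop = FALSE] - mesh$vertices[f[, 1], , drop = FALSE],
    mesh$vertices[f[, 3], , drop = FALSE] - mesh$vertices[f[, 1], , drop = FALSE]))
  ctr <- colMeans(mesh$vertices)
  fc <- (mesh$vertices[f[, 1], , drop = FALSE] +
         mesh$vertices[f[, 2], , drop = FALSE] +
         mesh$vertices[f[, 3], , drop = FALSE]) / 3
  outward <- rowSums(fn * sweep(fc, 2, ctr)) > 0
  if (mean(outward) < 0.5) mesh$faces <- f[, c(1, 3, 2), drop = FALSE]
  mesh
}

mesh_area <- function(mesh) sum(row_norms(face_normals(mesh))) / 2
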
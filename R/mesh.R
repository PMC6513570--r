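#' Triangle surface mesh
#'
#' Vertices are 3D points in physical nm; faces index vertices (1-based).
#' Surface area and volume ([mesh_surface_area()], [mesh_volume()]) require
#' a closed, consistently oriented mesh, which is what [mesh_from_mask()]
#' produces.
#'
#' @param vertices numeric matrix, n x 3 (nm).
#' @param faces integer matrix, m x 3, rows are triangles.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3L) stop("vertices must be n x 3", call. = FALSE)
  if (nrow(faces) > 0 &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range", call. = FALSE)
  structure(list(vertices = vertices, faces = faces),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (mesh_is_closed(x)) ", closed" else ", open"))
  invisible(x)
}

# every undirected edge must be shared by exactly two faces
mesh_boundary_edge_count <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(0L)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  nv <- nrow(mesh$vertices)
  key <- pmin(e[, 1], e[, 2]) * (nv + 1) + pmax(e[, 1], e[, 2])
  counts <- rle(sort(key))$lengths
  sum(counts != 2L)
}

#' Is a mesh closed (watertight)?
#' @param mesh a [surface_mesh()].
#' @return logical.
#' @export
mesh_is_closed <- function(mesh) {
  nrow(mesh$faces) > 0 && mesh_boundary_edge_count(mesh) == 0L
}

triangle_cross_products <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  u <- v[f[, 2], , drop = FALSE] - a
  w <- v[f[, 3], , drop = FALSE] - a
  cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
        u[, 3] * w[, 1] - u[, 1] * w[, 3],
        u[, 1] * w[, 2] - u[, 2] * w[, 1])
}

#' Mesh surface area
#'
#' Sum of triangle areas, in nm^2.
#'
#' @param mesh a closed [surface_mesh()].
#' @return surface area (nm^2).
#' @export
mesh_surface_area <- function(mesh) {
  stop_if_open(mesh)
  cr <- triangle_cross_products(mesh)
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Mesh volume
#'
#' Enclosed volume by the divergence theorem, in nm^3. An inward-oriented
#' mesh yields a negative signed volume; the absolute value is returned so
#' orientation conventions of external files do not flip the sign.
#'
#' @param mesh a closed [surface_mesh()].
#' @return volume (nm^3), positive.
#' @export
mesh_volume <- function(mesh) {
  stop_if_open(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  cr <- triangle_cross_products(mesh)
  abs(sum(rowSums(a * cr)) / 6)
}

stop_if_open <- function(mesh) {
  nb <- mesh_boundary_edge_count(mesh)
  if (nrow(mesh$faces) == 0 || nb > 0)
    stop(sprintf("mesh is not closed (%d boundary edge(s))", nb),
         call. = FALSE)
  invisible(TRUE)
}

#' Write a mesh to OBJ, STL (ASCII) or PLY (ASCII)
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @param format `"obj"`, `"stl"` or `"ply"`; default from extension.
#' @return `path`, invisibly. Warns (does not error) on an open mesh.
#' @export
write_mesh <- function(mesh, path,
                       format = tolower(tools::file_ext(path))) {
  stopifnot(inherits(mesh, "surface_mesh"))
  format <- match.arg(format, c("obj", "stl", "ply"))
  if (!mesh_is_closed(mesh))
    warning("writing an open (non-watertight) mesh", call. = FALSE)
  v <- mesh$vertices; f <- mesh$faces
  lines <- switch(format,
    obj = c(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
            sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])),
    ply = c("ply", "format ascii 1.0",
            sprintf("element vertex %d", nrow(v)),
            "property float x", "property float y", "property float z",
            sprintf("element face %d", nrow(f)),
            "property list uchar int vertex_indices", "end_header",
            sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
            sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)),
    stl = {
      a <- v[f[, 1], , drop = FALSE]
      b <- v[f[, 2], , drop = FALSE]
      cc <- v[f[, 3], , drop = FALSE]
      cr <- triangle_cross_products(mesh)
      nrm <- cr / pmax(sqrt(rowSums(cr^2)), .Machine$double.eps)
      body <- as.vector(rbind(
        sprintf("facet normal %.9g %.9g %.9g", nrm[, 1], nrm[, 2], nrm[, 3]),
        "outer loop",
        sprintf("vertex %.9g %.9g %.9g", a[, 1], a[, 2], a[, 3]),
        sprintf("vertex %.9g %.9g %.9g", b[, 1], b[, 2], b[, 3]),
        sprintf("vertex %.9g %.9g %.9g", cc[, 1], cc[, 2], cc[, 3]),
        "endloop", "endfacet"))
      c("solid mesh", body, "endsolid mesh")
    })
  writeLines(lines, path)
  invisible(path)
}

#' Read a mesh from OBJ, STL (ASCII) or PLY (ASCII)
#'
#' STL stores triangle soup; identical vertex coordinates are merged on
#' read so connectivity (and closedness) is recovered.
#'
#' @param path input path.
#' @return A [surface_mesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty mesh file", call. = FALSE)
  switch(ext,
    obj = {
      vl <- grep("^v ", lines, value = TRUE)
      fl <- grep("^f ", lines, value = TRUE)
      if (!length(vl) || !length(fl))
        stop("unreadable OBJ file", call. = FALSE)
      v <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(p)
        as.numeric(p[2:4])))
      f <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(p)
        as.integer(sub("/.*", "", p[2:4]))))
      surface_mesh(v, f)
    },
    ply = {
      endh <- match("end_header", trimws(lines))
      nv <- as.integer(sub("element vertex ", "",
                           grep("^element vertex", lines, value = TRUE)))
      nf <- as.integer(sub("element face ", "",
                           grep("^element face", lines, value = TRUE)))
      if (is.na(endh) || !length(nv) || !length(nf) ||
          length(lines) < endh + nv + nf)
        stop("unreadable PLY file", call. = FALSE)
      v <- do.call(rbind, lapply(strsplit(trimws(
        lines[endh + seq_len(nv)]), "\\s+"), function(p)
          as.numeric(p[1:3])))
      f <- do.call(rbind, lapply(strsplit(trimws(
        lines[endh + nv + seq_len(nf)]), "\\s+"), function(p)
          as.integer(p[2:4]) + 1L))
      surface_mesh(v, f)
    },
    stl = {
      vl <- grep("^\\s*vertex ", lines, value = TRUE)
      if (length(vl) == 0 || length(vl) %% 3 != 0)
        stop("unreadable STL file", call. = FALSE)
      pts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                   function(p) as.numeric(p[2:4])))
      key <- apply(signif(pts, 10), 1, paste, collapse = "|")
      uid <- !duplicated(key)
      idx <- match(key, key[uid])
      surface_mesh(pts[uid, , drop = FALSE],
                   matrix(idx, ncol = 3, byrow = TRUE))
    },
    stop("unsupported mesh format: .", ext, call. = FALSE))
}
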
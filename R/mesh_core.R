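#' Colored triangular mesh
#'
#' The central data container of the pipeline: vertex positions in meters,
#' triangular faces as 1-based vertex index triples, and optional per-vertex
#' RGB colors with integer channels in 0--255 (the PLY `uchar` convention
#' used by depth-camera exports).
#'
#' @param vertices numeric matrix, one row per vertex, columns x, y, z (m).
#' @param faces integer matrix, one row per face, three 1-based vertex
#'   indices. No face may repeat a vertex.
#' @param vertex_colors optional integer matrix with one RGB row per vertex,
#'   channels in 0--255.
#' @return An object of class `trimesh`.
#' @export
trimesh <- function(vertices, faces, vertex_colors = NULL) {
  vertices <- as_matrix3(vertices, "vertices")
  storage.mode(vertices) <- "double"
  if (!all(is.finite(vertices)))
    stop("vertex coordinates must be finite")
  if (is.null(faces) || length(faces) == 0) {
    faces <- matrix(integer(0), ncol = 3)
  } else {
    faces <- as_matrix3(faces, "faces")
    storage.mode(faces) <- "integer"
  }
  nv <- nrow(vertices)
  if (nrow(faces) > 0) {
    bad <- which(faces < 1L | faces > nv, arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("face %d references vertex index %d (mesh has %d vertices)",
                   bad[1, 1], faces[bad[1, 1], bad[1, 2]], nv))
    rep_v <- faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
      faces[, 2] == faces[, 3]
    if (any(rep_v))
      stop(sprintf("face %d repeats a vertex", which(rep_v)[1]))
  }
  if (!is.null(vertex_colors)) {
    vertex_colors <- as_matrix3(vertex_colors, "vertex_colors")
    if (nrow(vertex_colors) != nv)
      stop("vertex_colors must have one row per vertex")
    if (any(vertex_colors < 0 | vertex_colors > 255))
      stop("color channels must lie in [0, 255]")
    storage.mode(vertex_colors) <- "integer"
  }
  structure(list(vertices = vertices, faces = faces,
                 vertex_colors = vertex_colors),
            class = "trimesh")
}

as_matrix3 <- function(x, what) {
  x <- as.matrix(x)
  if (ncol(x) != 3)
    stop(sprintf("%s must have 3 columns", what))
  dimnames(x) <- NULL
  x
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("<trimesh> %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (is.null(x$vertex_colors)) "" else ", RGB colors"))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)
n_faces <- function(mesh) nrow(mesh$faces)

#' Point cloud with optional per-point colors
#'
#' @param points numeric matrix of 3D coordinates (m).
#' @param colors optional per-point RGB matrix, channels in 0--255.
#' @return An object of class `pointcloud`.
#' @export
point_cloud <- function(points, colors = NULL) {
  if (is.null(points) || length(points) == 0) {
    points <- matrix(numeric(0), ncol = 3)
  } else {
    points <- as_matrix3(points, "points")
    storage.mode(points) <- "double"
    if (!all(is.finite(points))) stop("coordinates must be finite")
  }
  if (!is.null(colors)) {
    colors <- as_matrix3(colors, "colors")
    if (nrow(colors) != nrow(points))
      stop("colors must have exactly one entry per point")
    storage.mode(colors) <- "integer"
  }
  structure(list(points = points, colors = colors), class = "pointcloud")
}

#' @export
print.pointcloud <- function(x, ...) {
  cat(sprintf("<pointcloud> %d points%s\n", nrow(x$points),
              if (is.null(x$colors)) "" else ", RGB colors"))
  invisible(x)
}

# ---- geometry helpers ----------------------------------------------------

face_vertex <- function(mesh, corner) mesh$vertices[mesh$faces[, corner], ,
                                                    drop = FALSE]

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

face_areas <- function(mesh) {
  if (n_faces(mesh) == 0) return(numeric(0))
  a <- face_vertex(mesh, 1)
  cr <- cross3(face_vertex(mesh, 2) - a, face_vertex(mesh, 3) - a)
  0.5 * sqrt(rowSums(cr^2))
}

face_centroids <- function(mesh) {
  if (n_faces(mesh) == 0) return(matrix(numeric(0), ncol = 3))
  (face_vertex(mesh, 1) + face_vertex(mesh, 2) + face_vertex(mesh, 3)) / 3
}

# Undirected edge keys per face (3 per face), encoded as doubles
# (min_idx * nv + max_idx, exact below 2^53).
face_edge_keys <- function(mesh) {
  f <- mesh$faces
  nv <- as.numeric(n_vertices(mesh))
  e1 <- cbind(f[, 1], f[, 2])
  e2 <- cbind(f[, 2], f[, 3])
  e3 <- cbind(f[, 3], f[, 1])
  ed <- rbind(e1, e2, e3)
  lo <- pmin(ed[, 1], ed[, 2])
  hi <- pmax(ed[, 1], ed[, 2])
  matrix(as.numeric(lo) * nv + as.numeric(hi), ncol = 3)
}

# Pairs of faces sharing an undirected edge. Within a non-manifold edge run,
# consecutive faces are chained, which is sufficient for union-find.
adjacent_face_pairs <- function(mesh, keys = NULL) {
  m <- n_faces(mesh)
  if (m == 0) return(matrix(integer(0), ncol = 2))
  if (is.null(keys)) keys <- face_edge_keys(mesh)
  k <- as.vector(keys)
  fid <- rep.int(seq_len(m), 3L)
  o <- order(k, fid)
  k <- k[o]; fid <- fid[o]
  same <- k[-1] == k[-length(k)]
  if (!any(same)) return(matrix(integer(0), ncol = 2))
  i <- which(same)
  cbind(fid[i], fid[i + 1L])
}

#' Edge-connected components of a mesh
#'
#' Partitions the faces into components in which any two faces are linked by
#' a chain of shared (undirected) edges — the notion of "connected faces"
#' used when lifting the maize canopy out of a field scan. Component ids are
#' ordered by decreasing face count; ties break toward the component
#' containing the lowest face index.
#'
#' @param mesh a [trimesh()].
#' @return A `component_labeling`: list with `face_labels` (one id per face)
#'   and `n_components`.
#' @export
connected_components <- function(mesh) {
  m <- n_faces(mesh)
  if (m == 0)
    return(structure(list(face_labels = integer(0), n_components = 0L),
                     class = "component_labeling"))
  pairs <- adjacent_face_pairs(mesh)
  roots <- if (nrow(pairs) == 0) seq_len(m) else
    uf_components(pairs, m)
  relabel_components(roots)
}

# Map arbitrary root ids to 1..k ordered by decreasing size, ties by lowest
# contained face index.
relabel_components <- function(roots) {
  grp <- match(roots, unique(roots))
  size <- tabulate(grp)
  first <- match(seq_along(size), grp)
  ord <- order(-size, first)
  newid <- integer(length(size))
  newid[ord] <- seq_along(size)
  structure(list(face_labels = newid[grp],
                 n_components = length(size)),
            class = "component_labeling")
}

#' @export
print.component_labeling <- function(x, ...) {
  cat(sprintf("<component_labeling> %d faces in %d components\n",
              length(x$face_labels), x$n_components))
  invisible(x)
}

#' Remove degenerate faces and unreferenced vertices
#'
#' Drops topologically degenerate faces, faces with area below
#' `area_threshold` (numerically zero at scene scale), and vertices no face
#' refers to. Idempotent; an empty mesh passes through unchanged.
#'
#' @param mesh a [trimesh()].
#' @param area_threshold minimum face area in m^2 to keep.
#' @return A cleaned [trimesh()].
#' @export
clean_mesh <- function(mesh, area_threshold = 1e-12) {
  if (n_faces(mesh) == 0) return(drop_unreferenced(mesh))
  keep <- face_areas(mesh) >= area_threshold
  mesh$faces <- mesh$faces[keep, , drop = FALSE]
  drop_unreferenced(mesh)
}

drop_unreferenced <- function(mesh) {
  used <- sort(unique(as.vector(mesh$faces)))
  idx <- integer(n_vertices(mesh))
  idx[used] <- seq_along(used)
  mesh$vertices <- mesh$vertices[used, , drop = FALSE]
  if (!is.null(mesh$vertex_colors))
    mesh$vertex_colors <- mesh$vertex_colors[used, , drop = FALSE]
  if (nrow(mesh$faces) > 0)
    mesh$faces <- matrix(idx[mesh$faces], ncol = 3)
  mesh
}

#' Extract a sub-mesh by face indices
#'
#' Keeps the selected faces and the vertices they reference. The returned
#' mesh carries an `orig_faces` attribute mapping its faces back to the
#' face indices of the *original* input mesh, composing through repeated
#' subsetting — used to propagate ground-truth face labels through
#' cropping and quadrat splitting.
#'
#' @param mesh a [trimesh()].
#' @param face_idx integer (or logical) face selector.
#' @return A [trimesh()] with attribute `orig_faces`.
#' @export
submesh <- function(mesh, face_idx) {
  if (is.logical(face_idx)) face_idx <- which(face_idx)
  face_idx <- as.integer(face_idx)
  parent <- attr(mesh, "orig_faces")
  out <- mesh
  out$faces <- mesh$faces[face_idx, , drop = FALSE]
  out <- drop_unreferenced(out)
  attr(out, "orig_faces") <-
    if (is.null(parent)) face_idx else parent[face_idx]
  out
}

#' Concatenate meshes
#'
#' Stacks vertices and faces of several meshes into one. Colors are kept if
#' every part has them.
#'
#' @param meshes list of [trimesh()] objects.
#' @return A single [trimesh()].
#' @export
merge_meshes <- function(meshes) {
  meshes <- meshes[vapply(meshes, function(m) n_vertices(m) > 0, logical(1))]
  if (length(meshes) == 0) return(trimesh(matrix(numeric(0), ncol = 3), NULL))
  vs <- do.call(rbind, lapply(meshes, `[[`, "vertices"))
  off <- cumsum(c(0L, vapply(meshes, n_vertices, integer(1))))
  fs <- do.call(rbind, Map(function(m, o) m$faces + o,
                           meshes, off[seq_along(meshes)]))
  has_col <- vapply(meshes, function(m) !is.null(m$vertex_colors), logical(1))
  cols <- if (all(has_col))
    do.call(rbind, lapply(meshes, `[[`, "vertex_colors")) else NULL
  trimesh(vs, fs, cols)
}
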
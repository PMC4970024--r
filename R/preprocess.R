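#' Remove isolated points from a point cloud
#'
#' Implements the "no connection" rule used to despeckle fused depth-camera
#' clouds: a point with fewer than `min_neighbors` other points within
#' `radius` (default 1 cm, the reconstruction grid scale) is discarded.
#' Retained points are a subset of the input; the operation is idempotent
#' and order-independent.
#'
#' @param cloud a [point_cloud()].
#' @param radius neighbor search radius in meters.
#' @param min_neighbors minimum number of other points required within
#'   `radius` for a point to survive.
#' @return A filtered [point_cloud()].
#' @export
filter_isolated_points <- function(cloud, radius = 0.01, min_neighbors = 1) {
  stopifnot(inherits(cloud, "pointcloud"), radius > 0)
  if (nrow(cloud$points) == 0) return(cloud)
  keep <- neighbor_counts(cloud$points, radius) >= min_neighbors
  point_cloud(cloud$points[keep, , drop = FALSE],
              if (is.null(cloud$colors)) NULL
              else cloud$colors[keep, , drop = FALSE])
}

#' Remove isolated vertices from a mesh
#'
#' Entry point for inputs that arrive already meshed: the neighbor rule of
#' [filter_isolated_points()] is applied to the vertex set, failing
#' vertices are removed, and any face referencing a removed vertex is
#' dropped. Vertices that pass the test are kept even when no face refers
#' to them.
#'
#' @inheritParams filter_isolated_points
#' @param mesh a [trimesh()].
#' @return A filtered [trimesh()] whose `orig_faces` attribute maps kept
#'   faces back to the input.
#' @export
filter_isolated_vertices <- function(mesh, radius = 0.01, min_neighbors = 1) {
  stopifnot(inherits(mesh, "trimesh"), radius > 0)
  nv <- n_vertices(mesh)
  if (nv == 0) return(mesh)
  keep_v <- neighbor_counts(mesh$vertices, radius) >= min_neighbors
  idx <- integer(nv)
  idx[keep_v] <- seq_len(sum(keep_v))
  keep_f <- if (n_faces(mesh) > 0)
    keep_v[mesh$faces[, 1]] & keep_v[mesh$faces[, 2]] & keep_v[mesh$faces[, 3]]
  else logical(0)
  parent <- attr(mesh, "orig_faces")
  out <- trimesh(mesh$vertices[keep_v, , drop = FALSE],
                 if (any(keep_f))
                   matrix(idx[mesh$faces[keep_f, , drop = FALSE]], ncol = 3)
                 else NULL,
                 if (is.null(mesh$vertex_colors)) NULL
                 else mesh$vertex_colors[keep_v, , drop = FALSE])
  attr(out, "orig_faces") <-
    if (is.null(parent)) which(keep_f) else parent[keep_f]
  attr(out, "removed_vertices") <- which(!keep_v)
  out
}

# ---- frame pose ----------------------------------------------------------

#' Pose of the white sampling frame
#'
#' @param corners 4 x 3 matrix of corner coordinates (m), counterclockwise
#'   seen from above.
#' @param normal unit normal of the ground plane (z component positive).
#' @param offset plane offset: points x on the plane satisfy
#'   `sum(x * normal) == offset`.
#' @param side_length nominal frame side in meters.
#' @return An object of class `frame_pose` with a `ground_plane` field.
#' @export
frame_pose <- function(corners, normal, offset, side_length = NULL) {
  corners <- as_matrix3(corners, "corners")
  normal <- as.numeric(normal)
  normal <- normal / sqrt(sum(normal^2))
  if (normal[3] < 0) {
    normal <- -normal
    offset <- -offset
  }
  if (is.null(side_length)) {
    sides <- sqrt(rowSums((corners[c(2, 3, 4, 1), ] - corners)^2))
    side_length <- mean(sides)
  }
  structure(list(corners = corners,
                 ground_plane = list(normal = normal, offset = offset),
                 side_length = side_length),
            class = "frame_pose")
}

#' @export
print.frame_pose <- function(x, ...) {
  cat(sprintf("<frame_pose> side %.3f m, normal (%.3f, %.3f, %.3f)\n",
              x$side_length, x$ground_plane$normal[1],
              x$ground_plane$normal[2], x$ground_plane$normal[3]))
  invisible(x)
}

#' Height of points above a ground plane
#'
#' @param points n x 3 coordinate matrix.
#' @param plane a `ground_plane` list (`normal`, `offset`), e.g. from a
#'   [frame_pose()].
#' @return Numeric vector of signed perpendicular heights (m).
#' @export
plane_height <- function(points, plane) {
  as.vector(points %*% plane$normal) - plane$offset
}

#' In-frame coordinates of points
#'
#' Projects points into the frame's own 2D system: origin at corner 1,
#' u along corner 1 to 2, v along corner 1 to 4, h perpendicular height.
#'
#' @param frame a [frame_pose()].
#' @param points n x 3 coordinate matrix.
#' @return Matrix with columns `u`, `v`, `h`.
#' @export
frame_coords <- function(frame, points) {
  o <- frame$corners[1, ]
  ex <- frame$corners[2, ] - o
  ex <- ex / sqrt(sum(ex^2))
  n <- frame$ground_plane$normal
  ey <- c(n[2] * ex[3] - n[3] * ex[2],
          n[3] * ex[1] - n[1] * ex[3],
          n[1] * ex[2] - n[2] * ex[1])
  d <- sweep(points, 2, o)
  cbind(u = as.vector(d %*% ex), v = as.vector(d %*% ey),
        h = plane_height(points, frame$ground_plane))
}

white_vertex_mask <- function(colors, white_threshold = 200,
                              saturation_max = 30) {
  if (is.null(colors)) stop("mesh has no vertex colors")
  lo <- pmin(colors[, 1], colors[, 2], colors[, 3])
  hi <- pmax(colors[, 1], colors[, 2], colors[, 3])
  lo >= white_threshold & (hi - lo) <= saturation_max
}

# Minimum-area rotated rectangle of 2D points (rotating calipers over the
# convex hull). Returns the 4 corners, counterclockwise.
min_area_rect <- function(xy) {
  hull <- grDevices::chull(xy)
  h <- xy[hull, , drop = FALSE]
  nh <- nrow(h)
  best <- NULL
  best_area <- Inf
  for (i in seq_len(nh)) {
    e <- h[if (i == nh) 1 else i + 1, ] - h[i, ]
    len <- sqrt(sum(e^2))
    if (len < 1e-12) next
    ex <- e / len
    ey <- c(-ex[2], ex[1])
    u <- h %*% ex
    v <- h %*% ey
    area <- (max(u) - min(u)) * (max(v) - min(v))
    if (area < best_area) {
      best_area <- area
      best <- list(ex = ex, ey = ey, ur = range(u), vr = range(v))
    }
  }
  with(best, rbind(ur[1] * ex + vr[1] * ey,
                   ur[2] * ex + vr[1] * ey,
                   ur[2] * ex + vr[2] * ey,
                   ur[1] * ex + vr[2] * ey))
}

#' Detect the white sampling frame in a colored mesh
#'
#' Vertices are labeled white when all channels reach `white_threshold` and
#' the channel spread stays within `saturation_max` (low chroma, robust to
#' shading of a painted frame). A PCA plane is fitted to the white vertices,
#' their in-plane projection is enclosed in a minimum-area rotated
#' rectangle, and the rectangle is shrunk inward by the median distance of
#' white points to its boundary — recovering the band centerline, i.e. the
#' nominal 1 m x 1 m sampling square.
#'
#' @param mesh a colored [trimesh()].
#' @param white_threshold per-channel minimum for "white".
#' @param saturation_max maximum channel spread (max - min) for "white".
#' @param min_white_vertices detection fails below this count.
#' @return A [frame_pose()]; corners are ordered counterclockwise seen from
#'   above starting at the corner with the smallest x + y.
#' @export
detect_frame <- function(mesh, white_threshold = 200, saturation_max = 30,
                         min_white_vertices = 200) {
  white <- white_vertex_mask(mesh$vertex_colors, white_threshold,
                             saturation_max)
  if (sum(white) < min_white_vertices)
    stop("no frame found: too few white vertices")
  p <- mesh$vertices[white, , drop = FALSE]
  ctr <- colMeans(p)
  cen <- sweep(p, 2, ctr)
  ev <- eigen(crossprod(cen) / nrow(cen), symmetric = TRUE)
  normal <- ev$vectors[, 3]
  if (normal[3] < 0) normal <- -normal
  offset <- sum(normal * ctr)
  # in-plane basis
  e1 <- c(1, 0, 0) - normal[1] * normal
  if (sqrt(sum(e1^2)) < 1e-6) e1 <- c(0, 1, 0) - normal[2] * normal
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  xy <- cen %*% cbind(e1, e2)
  rect <- min_area_rect(xy)
  # shrink outer rectangle to the band centerline
  dists <- rect_boundary_distance(xy, rect)
  rect <- shrink_rect(rect, stats::median(dists))
  corners <- sweep(rect %*% t(cbind(e1, e2)), 2, ctr, "+")
  # snap corners onto the fitted plane
  hts <- plane_height(corners, list(normal = normal, offset = offset))
  corners <- corners - outer(hts, normal)
  corners <- order_corners_ccw(corners, normal)
  frame_pose(corners, normal, offset)
}

rect_boundary_distance <- function(xy, rect) {
  ex <- rect[2, ] - rect[1, ]
  sx <- sqrt(sum(ex^2)); ex <- ex / sx
  ey <- rect[4, ] - rect[1, ]
  sy <- sqrt(sum(ey^2)); ey <- ey / sy
  d <- sweep(xy, 2, rect[1, ])
  u <- d %*% ex
  v <- d %*% ey
  pmin(pmax(u, 0), pmax(sx - u, 0), pmax(v, 0), pmax(sy - v, 0))
}

shrink_rect <- function(rect, by) {
  ctr <- colMeans(rect)
  ex <- rect[2, ] - rect[1, ]
  sx <- sqrt(sum(ex^2)); ex <- ex / sx
  ey <- rect[4, ] - rect[1, ]
  sy <- sqrt(sum(ey^2)); ey <- ey / sy
  hx <- sx / 2 - by
  hy <- sy / 2 - by
  rbind(ctr - hx * ex - hy * ey, ctr + hx * ex - hy * ey,
        ctr + hx * ex + hy * ey, ctr - hx * ex + hy * ey)
}

order_corners_ccw <- function(corners, normal) {
  ctr <- colMeans(corners)
  rel <- sweep(corners, 2, ctr)
  # angle in the plane around the upward normal
  e1 <- rel[1, ] / sqrt(sum(rel[1, ]^2))
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  ang <- atan2(rel %*% e2, rel %*% e1)
  corners <- corners[order(ang), , drop = FALSE]
  start <- which.min(corners[, 1] + corners[, 2])
  corners[(seq_len(4) + start - 2L) %% 4L + 1L, , drop = FALSE]
}

# ---- cropping and quadrats -----------------------------------------------

#' Crop a scene mesh to the sampling frame
#'
#' Keeps exactly the faces whose centroid, projected onto the ground plane,
#' falls inside the frame rectangle; faces touching white (frame) vertices
#' are excluded so the frame itself never enters the analysis.
#'
#' @param mesh a colored [trimesh()].
#' @param frame a [frame_pose()].
#' @param white_threshold,saturation_max white-vertex rule, as in
#'   [detect_frame()].
#' @return The cropped [trimesh()] (with `orig_faces` attribute).
#' @export
crop_to_frame <- function(mesh, frame, white_threshold = 200,
                          saturation_max = 30) {
  stopifnot(inherits(frame, "frame_pose"))
  if (n_faces(mesh) == 0) stop("empty quadrat: nothing inside the frame")
  uv <- frame_coords(frame, face_centroids(mesh))
  su <- sqrt(sum((frame$corners[2, ] - frame$corners[1, ])^2))
  sv <- sqrt(sum((frame$corners[4, ] - frame$corners[1, ])^2))
  inside <- uv[, "u"] >= 0 & uv[, "u"] <= su &
    uv[, "v"] >= 0 & uv[, "v"] <= sv
  if (!is.null(mesh$vertex_colors)) {
    white <- white_vertex_mask(mesh$vertex_colors, white_threshold,
                               saturation_max)
    f <- mesh$faces
    inside <- inside & !(white[f[, 1]] | white[f[, 2]] | white[f[, 3]])
  }
  if (!any(inside)) stop("empty quadrat: nothing inside the frame")
  submesh(mesh, inside)
}

#' A 0.5 m x 0.5 m quadrat sample
#'
#' @param mesh the quadrat's [trimesh()].
#' @param quadrat_index integer 1--4.
#' @param position_label `"row"` or `"inter_row"` (field metadata).
#' @param frame the parent [frame_pose()].
#' @return An object of class `quadrat_sample`.
#' @export
quadrat_sample <- function(mesh, quadrat_index, position_label, frame) {
  position_label <- match.arg(position_label, c("row", "inter_row"))
  structure(list(mesh = mesh, quadrat_index = as.integer(quadrat_index),
                 position_label = position_label, frame = frame),
            class = "quadrat_sample")
}

#' @export
print.quadrat_sample <- function(x, ...) {
  cat(sprintf("<quadrat_sample> #%d (%s), %d faces\n", x$quadrat_index,
              x$position_label, n_faces(x$mesh)))
  invisible(x)
}

#' Split a cropped frame into four quadrats
#'
#' Each face is assigned to one of the four 0.5 m x 0.5 m quadrats by the
#' quadrant of its centroid in frame coordinates; the midlines use
#' half-open intervals so a centroid exactly on a midline goes to the
#' lower-index quadrat. The face sets are disjoint and their union is the
#' input face set, so total face count and area are conserved exactly.
#'
#' Quadrat indices count row-major from the frame origin: 1 = low-u/low-v,
#' 2 = high-u/low-v, 3 = low-u/high-v, 4 = high-u/high-v.
#'
#' @param mesh mesh already cropped with [crop_to_frame()].
#' @param frame a [frame_pose()].
#' @param labels character vector of four position labels (`"row"` /
#'   `"inter_row"`), one per quadrat index.
#' @return List of four [quadrat_sample()] objects.
#' @export
split_quadrats <- function(mesh, frame,
                           labels = c("row", "inter_row", "row",
                                      "inter_row")) {
  stopifnot(length(labels) == 4)
  uv <- frame_coords(frame, face_centroids(mesh))
  su <- sqrt(sum((frame$corners[2, ] - frame$corners[1, ])^2))
  sv <- sqrt(sum((frame$corners[4, ] - frame$corners[1, ])^2))
  hi_u <- uv[, "u"] >= su / 2
  hi_v <- uv[, "v"] >= sv / 2
  qidx <- 1L + hi_u + 2L * hi_v
  lapply(1:4, function(q)
    quadrat_sample(submesh(mesh, qidx == q), q, labels[q], frame))
}
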
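#' Excess-green vegetation index
#'
#' The standard agronomic color index ExG = 2G - R - B: strongly positive
#' on green vegetation, near zero on achromatic soil and on the white
#' frame.
#'
#' @param color an RGB triple, or an n x 3 matrix of RGB rows, channels in
#'   0--255.
#' @return Numeric ExG value(s).
#' @export
excess_green <- function(color) {
  if (is.null(dim(color))) {
    stopifnot(length(color) == 3)
    color <- matrix(color, ncol = 3)
  }
  if (any(color < 0 | color > 255)) stop("channels must lie in [0, 255]")
  as.numeric(2 * color[, 2] - color[, 1] - color[, 3])
}

#' Otsu threshold of an ExG sample
#'
#' Optional automatic alternative to the fixed ExG cut: maximizes
#' between-class variance over a 256-bin histogram of the index values.
#'
#' @param values numeric ExG values.
#' @return A single threshold on the ExG scale.
#' @export
exg_otsu_threshold <- function(values) {
  rng <- range(values)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = 257)
  h <- tabulate(findInterval(values, breaks, all.inside = TRUE), 256)
  w <- cumsum(h)
  mids <- (breaks[-1] + breaks[-257]) / 2
  m <- cumsum(h * mids)
  tot_w <- w[256]
  tot_m <- m[256]
  w1 <- w[-256]; m1 <- m[-256]
  w2 <- tot_w - w1
  valid <- w1 > 0 & w2 > 0
  between <- rep(-Inf, 255)
  between[valid] <- (tot_m * w1[valid] / tot_w - m1[valid])^2 /
    (w1[valid] * w2[valid])
  mids[which.max(between)]
}

# Per-face vegetation vote: a face counts as vegetation when at least 2 of
# its 3 vertices pass the ExG threshold (keeps the partition well defined
# on color-gradient boundaries).
face_vegetation <- function(mesh, exg_threshold = 20) {
  veg_v <- excess_green(mesh$vertex_colors) > exg_threshold
  f <- mesh$faces
  (veg_v[f[, 1]] + veg_v[f[, 2]] + veg_v[f[, 3]]) >= 2
}

#' Isolate maize by height selection of connected faces
#'
#' Maize is considerably taller than the weeds, so its canopy is lifted out
#' of the quadrat by height: faces with any vertex above `height_threshold`
#' (measured perpendicular to the ground plane) seed a region growth over
#' edge-connected faces. Growth is restricted to vegetation-flagged faces
#' (ExG vote) and never enters faces lying entirely below
#' `ground_clearance`, which prevents the flood fill from leaking through
#' soil where a stalk meets the ground.
#'
#' @param sample a [quadrat_sample()] (or a bare [trimesh()] together with
#'   `frame`).
#' @param height_threshold seed height in m; default 0.30, the midpoint
#'   between the study's weed maximum (0.20 m) and maize minimum (0.40 m).
#' @param exg_threshold ExG vegetation cut, see [excess_green()].
#' @param ground_clearance faces entirely below this height never join a
#'   maize region (m).
#' @param frame optional [frame_pose()] when `sample` is a bare mesh.
#' @return List with `maize_mesh`, `remainder` (both [trimesh()] with
#'   `orig_faces`), and `maize_faces` (logical per input face).
#' @export
select_maize <- function(sample, height_threshold = 0.30,
                         exg_threshold = 20, ground_clearance = 0.02,
                         frame = NULL) {
  if (inherits(sample, "quadrat_sample")) {
    mesh <- sample$mesh
    frame <- sample$frame
  } else mesh <- sample
  if (is.null(frame)) stop("a frame (ground plane) is required")
  plane <- frame$ground_plane
  nf <- n_faces(mesh)
  if (nf == 0)
    return(list(maize_mesh = submesh(mesh, integer(0)),
                remainder = submesh(mesh, integer(0)),
                maize_faces = logical(0)))
  h <- plane_height(mesh$vertices, plane)
  f <- mesh$faces
  grow <- face_vegetation(mesh, exg_threshold) &
    !(h[f[, 1]] < ground_clearance & h[f[, 2]] < ground_clearance &
        h[f[, 3]] < ground_clearance)
  seed <- grow & (h[f[, 1]] > height_threshold |
                    h[f[, 2]] > height_threshold |
                    h[f[, 3]] > height_threshold)
  maize <- logical(nf)
  if (any(seed)) {
    grow_idx <- which(grow)
    sub <- submesh(mesh, grow_idx)
    lab <- connected_components(sub)$face_labels
    seed_labels <- unique(lab[match(which(seed), grow_idx)])
    maize[grow_idx[lab %in% seed_labels]] <- TRUE
  }
  list(maize_mesh = submesh(mesh, maize),
       remainder = submesh(mesh, !maize),
       maize_faces = maize)
}

#' Separate weeds from soil by color
#'
#' After maize removal the remaining vegetation is too low to separate from
#' the soil microrelief by height, so an RGB filter selects the green
#' parts: a face is weed when at least 2 of its 3 vertices exceed the ExG
#' threshold; everything else (soil and frame remnants) is soil.
#'
#' @param remainder colored [trimesh()] left by [select_maize()].
#' @param exg_threshold ExG vegetation cut.
#' @return List with `weed_mesh`, `soil_mesh`, and `weed_faces` (logical
#'   per input face).
#' @export
select_weeds <- function(remainder, exg_threshold = 20) {
  if (n_faces(remainder) == 0)
    return(list(weed_mesh = submesh(remainder, integer(0)),
                soil_mesh = submesh(remainder, integer(0)),
                weed_faces = logical(0)))
  if (is.null(remainder$vertex_colors)) stop("mesh has no vertex colors")
  weed <- face_vegetation(remainder, exg_threshold)
  list(weed_mesh = submesh(remainder, weed),
       soil_mesh = submesh(remainder, !weed),
       weed_faces = weed)
}

#' Segment a quadrat into maize, weeds, and soil
#'
#' The dual methodology: height selection of connected faces isolates the
#' maize, then the excess-green filter splits the remainder into weeds and
#' soil. The three face sets are pairwise disjoint and cover the input.
#'
#' @inheritParams select_maize
#' @return A `segmentation_result`: list with `maize_mesh`, `weed_mesh`,
#'   `soil_mesh` and `face_assignment` (factor `maize`/`weed`/`soil` per
#'   input face).
#' @export
segment_sample <- function(sample, height_threshold = 0.30,
                           exg_threshold = 20, ground_clearance = 0.02,
                           frame = NULL) {
  mz <- select_maize(sample, height_threshold, exg_threshold,
                     ground_clearance, frame)
  wd <- select_weeds(mz$remainder, exg_threshold)
  mesh <- if (inherits(sample, "quadrat_sample")) sample$mesh else sample
  assignment <- rep("soil", n_faces(mesh))
  assignment[mz$maize_faces] <- "maize"
  rem_idx <- which(!mz$maize_faces)
  assignment[rem_idx[wd$weed_faces]] <- "weed"
  structure(list(maize_mesh = mz$maize_mesh,
                 weed_mesh = wd$weed_mesh,
                 soil_mesh = wd$soil_mesh,
                 face_assignment = factor(assignment,
                                          levels = c("maize", "weed",
                                                     "soil"))),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  tb <- table(x$face_assignment)
  cat(sprintf("<segmentation_result> maize %d, weed %d, soil %d faces\n",
              tb[["maize"]], tb[["weed"]], tb[["soil"]]))
  invisible(x)
}

#' Height summary of a weed mesh
#'
#' Heights of all weed vertices above the ground plane, summarized as the
#' per-quadrat maximum, 90th percentile, and mean — the candidate features
#' for discriminating grass from broad-leaved infestations.
#'
#' @param weed_mesh non-empty [trimesh()].
#' @param ground_plane a `ground_plane` list (`normal`, `offset`).
#' @return List with `max_height`, `p90_height`, `mean_height` (m).
#' @export
weed_height_features <- function(weed_mesh, ground_plane) {
  if (n_vertices(weed_mesh) == 0) stop("no weed vertices")
  h <- plane_height(weed_mesh$vertices, ground_plane)
  list(max_height = max(h),
       p90_height = as.numeric(quantile(h, 0.9, names = FALSE)),
       mean_height = mean(h))
}
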
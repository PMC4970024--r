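# Edge bookkeeping: undirected edges with use counts, plus the lo/hi vertex
# pair so face traversal direction can be recovered.
mesh_edge_table <- function(mesh) {
  f <- mesh$faces
  ed <- rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]),
              cbind(f[, 3], f[, 1]))
  lo <- pmin(ed[, 1], ed[, 2])
  hi <- pmax(ed[, 1], ed[, 2])
  key <- as.numeric(lo) * n_vertices(mesh) + as.numeric(hi)
  face <- rep.int(seq_len(nrow(f)), 3L)
  list(key = key, lo = lo, hi = hi, face = face)
}

#' Is a mesh watertight?
#'
#' A mesh is watertight (closed) when every edge is shared by exactly two
#' faces — the precondition for divergence-theorem volume.
#'
#' @param mesh a [trimesh()].
#' @return TRUE/FALSE.
#' @export
is_watertight <- function(mesh) {
  if (n_faces(mesh) == 0) return(FALSE)
  et <- mesh_edge_table(mesh)
  all(table_counts(et$key) == 2L)
}

table_counts <- function(key) {
  k <- sort(key)
  r <- rle(k)
  r$lengths
}

# Coherent outward orientation by breadth-first propagation across shared
# edges, then a global sign fix per connected component (positive enclosed
# volume). Returns the face matrix with rows flipped as needed.
orient_faces_coherently <- function(mesh) {
  nf <- n_faces(mesh)
  f <- mesh$faces
  if (nf == 0) return(f)
  et <- mesh_edge_table(mesh)
  o <- order(et$key, et$face)
  k <- et$key[o]; fid <- et$face[o]; lo <- et$lo[o]; hi <- et$hi[o]
  same <- which(k[-1] == k[-length(k)])
  if (length(same) == 0) pairs <- matrix(integer(0), ncol = 2) else
    pairs <- cbind(same, same + 1L)
  # traversal direction of each edge slot: TRUE if the face walks lo -> hi
  dirs <- logical(length(k))
  if (length(k) > 0) {
    f1 <- f[fid, 1]; f2 <- f[fid, 2]; f3 <- f[fid, 3]
    dirs <- (f1 == lo & f2 == hi) | (f2 == lo & f3 == hi) |
      (f3 == lo & f1 == hi)
  }
  np <- nrow(pairs)
  adj_from <- c(fid[pairs[, 1]], fid[pairs[, 2]])
  adj_to <- c(fid[pairs[, 2]], fid[pairs[, 1]])
  adj_dir_from <- c(dirs[pairs[, 1]], dirs[pairs[, 2]])
  adj_dir_to <- c(dirs[pairs[, 2]], dirs[pairs[, 1]])
  # CSR-style adjacency for a fast integer BFS
  o2 <- order(adj_from)
  adj_to <- adj_to[o2]
  adj_dir_from <- adj_dir_from[o2]
  adj_dir_to <- adj_dir_to[o2]
  ptr <- c(0L, cumsum(tabulate(adj_from[o2], nf)))
  flip <- logical(nf)
  comp <- integer(nf)
  visited <- logical(nf)
  ncomp <- 0L
  queue <- integer(nf)
  for (s in seq_len(nf)) {
    if (visited[s]) next
    ncomp <- ncomp + 1L
    visited[s] <- TRUE
    comp[s] <- ncomp
    queue[1] <- s
    head <- 1L; tail <- 1L
    while (head <= tail) {
      cur <- queue[head]; head <- head + 1L
      lo <- ptr[cur] + 1L; hi <- ptr[cur + 1L]
      if (lo <= hi) for (sl in lo:hi) {
        nb <- adj_to[sl]
        if (!visited[nb]) {
          visited[nb] <- TRUE
          comp[nb] <- ncomp
          # consistent orientation: shared edge traversed oppositely
          flip[nb] <- (adj_dir_to[sl] == xor(adj_dir_from[sl], flip[cur]))
          tail <- tail + 1L
          queue[tail] <- nb
        }
      }
    }
  }
  f_or <- f
  if (any(flip)) f_or[flip, ] <- f_or[flip, c(1, 3, 2)]
  # global sign per component: enclosed volume must be positive
  contrib <- face_volume_contrib(mesh$vertices, f_or)
  csum <- vapply(split(contrib, comp), sum, numeric(1))
  neg <- as.integer(names(csum)[csum < 0])
  if (length(neg) > 0) {
    flip2 <- comp %in% neg
    f_or[flip2, ] <- f_or[flip2, c(1, 3, 2)]
  }
  f_or
}

face_volume_contrib <- function(v, f) {
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  (a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) +
     a[, 2] * (b[, 3] * c3[, 1] - b[, 1] * c3[, 3]) +
     a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
}

#' Enclosed volume of a closed mesh (polyhedral mass properties)
#'
#' Divergence-theorem volume: the sum over triangles of one sixth of the
#' determinant of their vertex position vectors. Faces are first reoriented
#' coherently and the global sign fixed, so the input winding does not
#' matter; the orientation sign of the *input* is reported in the
#' `orientation_sign` attribute.
#'
#' @param mesh a closed [trimesh()] (every edge shared by exactly two
#'   faces). Open meshes raise an error directing to [close_to_ground()].
#' @return Volume in m^3 (non-negative), with attribute
#'   `orientation_sign`.
#' @export
signed_volume <- function(mesh) {
  if (n_faces(mesh) == 0) return(structure(0, orientation_sign = 0))
  if (!is_watertight(mesh))
    stop("mesh not watertight: close it first (see close_to_ground)")
  raw_total <- sum(face_volume_contrib(mesh$vertices, mesh$faces))
  f_or <- orient_faces_coherently(mesh)
  vol <- sum(face_volume_contrib(mesh$vertices, f_or))
  structure(vol, orientation_sign = sign(raw_total))
}

# Fast private path for generator-built meshes with known coherent outward
# orientation (no watertightness or orientation pass).
signed_volume_raw <- function(vertices, faces) {
  sum(face_volume_contrib(vertices, faces))
}

# ---- watertight closure --------------------------------------------------

boundary_error <- function(msg) {
  stop(structure(class = c("weedvol_boundary_error", "error",
                           "condition"),
                 list(message = msg, call = NULL)))
}

# Decompose the boundary edges into closed loops by walking unused edges.
# Non-manifold boundary vertices (even degree > 2, e.g. two sensor-dropout
# holes meeting at a vertex) are traversed by pairing edges greedily; the
# final watertightness check in close_to_ground validates the result.
boundary_loops <- function(mesh) {
  et <- mesh_edge_table(mesh)
  o <- order(et$key)
  k <- et$key[o]
  r <- rle(k)
  single_end <- cumsum(r$lengths)[r$lengths == 1L]
  if (length(single_end) == 0) return(list())
  pos <- o[single_end]
  lo <- et$lo[pos]
  hi <- et$hi[pos]
  ne <- length(lo)
  verts <- sort(unique(c(lo, hi)))
  vl <- match(lo, verts)
  vh <- match(hi, verts)
  deg <- tabulate(c(vl, vh), length(verts))
  if (any(deg %% 2L != 0L))
    boundary_error("boundary edges do not pair up")
  inc <- split(rep(seq_len(ne), 2L), c(vl, vh))
  used <- logical(ne)
  loops <- list()
  pos <- integer(length(verts)) # position of a vertex in the current path
  for (e0 in seq_len(ne)) {
    if (used[e0]) next
    used[e0] <- TRUE
    start <- vl[e0]
    cur <- vh[e0]
    path <- c(start, cur)
    pos[start] <- 1L
    pos[cur] <- 2L
    while (cur != start) {
      cand <- inc[[cur]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0)
        boundary_error("boundary walk failed to close a loop")
      nxt_e <- cand[1]
      used[nxt_e] <- TRUE
      nxt <- if (vl[nxt_e] == cur) vh[nxt_e] else vl[nxt_e]
      p <- pos[nxt]
      if (nxt == start) break
      if (p > 0L) {
        # revisited vertex: pinch the enclosed cycle off as its own
        # simple loop and continue from the revisit point
        sub <- path[p:length(path)]
        if (length(sub) < 3L)
          boundary_error("degenerate boundary cycle")
        loops[[length(loops) + 1L]] <- verts[sub]
        pos[sub[-1L]] <- 0L
        path <- path[seq_len(p)]
      } else {
        path <- c(path, nxt)
        pos[nxt] <- length(path)
      }
      cur <- nxt
    }
    if (length(path) < 3L) boundary_error("degenerate boundary cycle")
    loops[[length(loops) + 1L]] <- verts[path]
    pos[path] <- 0L
  }
  loops
}

#' Close an open canopy mesh against the ground plane
#'
#' Depth-camera canopy surfaces are open; for mass-properties volume they
#' are sealed here. Boundary loops that reach down to the ground — where
#' the canopy surface ends at the soil — are projected onto the ground
#' plane and sealed with side walls and a triangulated base. Loops that
#' stay clear of the ground (sensor dropouts, cuts through foliage at a
#' quadrat border) are patched in place with a centroid fan, so no
#' spurious volume is added beneath them. An already-closed mesh is
#' returned unchanged.
#'
#' @param mesh an open [trimesh()].
#' @param ground_plane a `ground_plane` list (`normal`, `offset`).
#' @param patch_max_vertices,patch_max_diameter loops at most this long and
#'   this wide (bounding-box diagonal, m) are always patched in place.
#' @param ground_attach loops whose lowest vertex stays above this height
#'   (m) are patched in place instead of projected to the ground.
#' @return A watertight [trimesh()] with attribute `added_faces` (indices
#'   of the sealing faces). A non-manifold boundary raises a condition of
#'   class `weedvol_boundary_error` (callers fall back to
#'   [prism_volume()]).
#' @export
close_to_ground <- function(mesh, ground_plane, patch_max_vertices = 12,
                            patch_max_diameter = 0.04,
                            ground_attach = 0.05) {
  if (n_faces(mesh) == 0) return(mesh)
  if (is_watertight(mesh)) return(mesh)
  loops <- boundary_loops(mesh)
  v <- mesh$vertices
  cols <- mesh$vertex_colors
  new_f <- list()
  for (loop in loops) {
    pts <- v[loop, , drop = FALSE]
    diam <- sqrt(sum((apply(pts, 2, max) - apply(pts, 2, min))^2))
    k <- length(loop)
    nxt <- c(loop[-1], loop[1])
    small <- k <= patch_max_vertices && diam <= patch_max_diameter
    airborne <- min(plane_height(pts, ground_plane)) > ground_attach
    if (small || airborne) {
      # small hole: centroid fan
      cidx <- nrow(v) + 1L
      v <- rbind(v, colMeans(pts))
      if (!is.null(cols))
        cols <- rbind(cols, round(colMeans(cols[loop, , drop = FALSE])))
      new_f[[length(new_f) + 1L]] <- cbind(loop, nxt, cidx)
    } else {
      # ground closure: project the loop, add walls and a base fan
      h <- plane_height(pts, ground_plane)
      proj <- pts - outer(h, ground_plane$normal)
      base_idx <- nrow(v) + seq_len(k)
      v <- rbind(v, proj)
      if (!is.null(cols)) cols <- rbind(cols, cols[loop, , drop = FALSE])
      cidx <- nrow(v) + 1L
      v <- rbind(v, colMeans(proj))
      if (!is.null(cols))
        cols <- rbind(cols, round(colMeans(cols[loop, , drop = FALSE])))
      nxt_base <- c(base_idx[-1], base_idx[1])
      new_f[[length(new_f) + 1L]] <- rbind(
        cbind(loop, nxt, nxt_base),
        cbind(loop, nxt_base, base_idx),
        cbind(nxt_base, rep(cidx, k), base_idx))
    }
  }
  add <- do.call(rbind, new_f)
  out <- trimesh(v, rbind(mesh$faces, add), cols)
  if (!is_watertight(out))
    stop(structure(class = c("weedvol_boundary_error", "error", "condition"),
                   list(message = "closure did not produce a watertight mesh",
                        call = sys.call(-1))))
  attr(out, "added_faces") <- n_faces(mesh) + seq_len(nrow(add))
  out
}

#' Prism volume of a height-field surface
#'
#' Documented fallback for pathological boundaries: the volume between the
#' surface and the ground plane, as the sum over faces of projected area
#' times mean vertex height. Assumes the mesh projects injectively onto
#' the plane.
#'
#' @param mesh a [trimesh()].
#' @param ground_plane a `ground_plane` list.
#' @return Volume in m^3.
#' @export
prism_volume <- function(mesh, ground_plane) {
  if (n_faces(mesh) == 0) return(0)
  n <- ground_plane$normal
  e1 <- c(1, 0, 0) - n[1] * n
  if (sqrt(sum(e1^2)) < 1e-6) e1 <- c(0, 1, 0) - n[2] * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  uv <- mesh$vertices %*% cbind(e1, e2)
  h <- plane_height(mesh$vertices, ground_plane)
  f <- mesh$faces
  ax <- uv[f[, 2], 1] - uv[f[, 1], 1]; ay <- uv[f[, 2], 2] - uv[f[, 1], 2]
  bx <- uv[f[, 3], 1] - uv[f[, 1], 1]; by <- uv[f[, 3], 2] - uv[f[, 1], 2]
  area2d <- 0.5 * abs(ax * by - ay * bx)
  hmean <- (h[f[, 1]] + h[f[, 2]] + h[f[, 3]]) / 3
  sum(area2d * hmean)
}

#' Voxel-counting volume (independent oracle)
#'
#' Counts voxel centers inside a closed mesh (vertical ray parity) and
#' multiplies by the voxel volume. Used as an independent cross-check of
#' [signed_volume()] in validation; not a production path.
#'
#' @param mesh a closed [trimesh()].
#' @param voxel voxel edge length in m.
#' @return Volume in m^3.
#' @export
voxel_volume <- function(mesh, voxel = 0.005) {
  if (n_faces(mesh) == 0) return(0)
  if (!is_watertight(mesh))
    stop("mesh not watertight: close it first (see close_to_ground)")
  lo <- apply(mesh$vertices, 2, min)
  hi <- apply(mesh$vertices, 2, max)
  # grid anchored to the absolute lattice (multiples of the voxel size),
  # so the oracle does not depend on the object's bounding box
  gx <- seq((floor(lo[1] / voxel) + 0.5) * voxel, hi[1], by = voxel)
  gy <- seq((floor(lo[2] / voxel) + 0.5) * voxel, hi[2], by = voxel)
  gz <- seq((floor(lo[3] / voxel) + 0.5) * voxel, hi[3], by = voxel)
  ncent <- length(gx) * length(gy) * length(gz)
  if (ncent > 2e7) stop("voxel grid too large; increase `voxel`")
  centers <- as.matrix(expand.grid(x = gx, y = gy, z = gz,
                                   KEEP.OUT.ATTRS = FALSE))
  inside <- points_in_mesh(mesh$vertices, mesh$faces, centers)
  sum(inside) * voxel^3
}

#' Per-quadrat volume report
#'
#' Volumes of the maize mesh, the weed mesh, and their union, each sealed
#' with [close_to_ground()] and measured with [signed_volume()] (prism
#' fallback on pathological boundaries; the method actually used is
#' recorded).
#'
#' @param seg a `segmentation_result` from [segment_sample()].
#' @param ground_plane a `ground_plane` list.
#' @param method `"divergence"` (closure + mass properties, default) or
#'   `"prism"`.
#' @return A `volume_report`: list with `maize_volume`, `weed_volume`,
#'   `total_volume` (m^3) and `method`.
#' @export
quadrat_volume_report <- function(seg, ground_plane,
                                  method = c("divergence", "prism")) {
  method <- match.arg(method)
  used <- method
  vol_of <- function(mesh) {
    if (n_faces(mesh) == 0) return(0)
    if (method == "prism") return(prism_volume(mesh, ground_plane))
    tryCatch(as.numeric(signed_volume(close_to_ground(mesh, ground_plane))),
             weedvol_boundary_error = function(e) {
               warning("falling back to prism volume: ",
                       conditionMessage(e))
               used <<- "prism"
               prism_volume(mesh, ground_plane)
             })
  }
  union_mesh <- merge_meshes(list(seg$maize_mesh, seg$weed_mesh))
  structure(list(maize_volume = vol_of(seg$maize_mesh),
                 weed_volume = vol_of(seg$weed_mesh),
                 total_volume = vol_of(union_mesh),
                 method = used),
            class = "volume_report")
}

#' @export
print.volume_report <- function(x, ...) {
  cat(sprintf(
    "<volume_report> maize %.1f cm^3, weed %.1f cm^3, total %.1f cm^3 (%s)\n",
    x$maize_volume * 1e6, x$weed_volume * 1e6, x$total_volume * 1e6,
    x$method))
  invisible(x)
}
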
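#' Configuration of a synthetic quadrat scene
#'
#' Describes one 1 m x 1 m framed sampling scene the way the field study
#' laid them out: a tilled-soil height field with microrelief, a white
#' frame band, a maize row crossing the two "row" quadrats, and weed
#' cover per quadrat. Heights follow the measured stand: maize 0.40--0.55
#' m, grasses up to 0.20 m, broad-leaved weeds below 0.10 m.
#'
#' @param n_maize total maize plants in the scene (split across the two
#'   row quadrats).
#' @param maize_height_range,grass_height_range,broadleaf_height_range
#'   plant height ranges in m.
#' @param weed_density_range weed plants per infested quadrat (min, max).
#' @param weed_class_by_quadrat character of length 4 over
#'   `"none"`, `"grass"`, `"broadleaf"`, `"mixture"`; quadrat order is
#'   row-major from the frame origin, quadrats 1 and 3 carry the maize
#'   row.
#' @param soil_relief_amplitude microrelief half-amplitude in m (soil
#'   height varies in +-amplitude around the frame plane).
#' @param color_noise_sd Gaussian RGB channel noise (0--255 scale).
#' @param outlier_fraction fraction of isolated sensor outlier points
#'   injected by [add_sensor_noise()].
#' @param depth_noise_sd sensor depth jitter along the view axis (m), used
#'   by [add_sensor_noise()].
#' @param dropout_fraction fraction of faces lost to sensor dropout.
#' @param point_spacing surface sampling grid in m; soil, frame, and plant
#'   surfaces are all tessellated at this scale, emulating the uniform
#'   sampling of a fused depth reconstruction.
#' @param maize_density_factor,weed_density_factor dry biomass per unit
#'   mesh volume (g/m^3).
#' @param biomass_cv multiplicative biomass noise (sd of the relative
#'   error) used when a scene is generated standalone.
#' @param seed integer RNG seed; identical configs reproduce identical
#'   scenes byte for byte.
#' @return A `scene_config` list.
#' @export
scene_config <- function(n_maize = 6,
                         maize_height_range = c(0.40, 0.55),
                         grass_height_range = c(0.10, 0.20),
                         broadleaf_height_range = c(0.02, 0.10),
                         weed_density_range = c(4, 12),
                         weed_class_by_quadrat = c("grass", "broadleaf",
                                                   "mixture", "none"),
                         soil_relief_amplitude = 0.02,
                         color_noise_sd = 5,
                         outlier_fraction = 0.01,
                         depth_noise_sd = 0.003,
                         dropout_fraction = 0.002,
                         point_spacing = 0.007,
                         maize_density_factor = 60000,
                         weed_density_factor = 90000,
                         biomass_cv = 0.2,
                         seed = 1) {
  chk_range <- function(r, name) {
    if (length(r) != 2 || any(r <= 0) || r[1] > r[2])
      stop(sprintf("%s must be a positive ordered range", name))
  }
  chk_range(maize_height_range, "maize_height_range")
  chk_range(grass_height_range, "grass_height_range")
  chk_range(broadleaf_height_range, "broadleaf_height_range")
  chk_range(weed_density_range, "weed_density_range")
  stopifnot(outlier_fraction >= 0, outlier_fraction < 1,
            dropout_fraction >= 0, dropout_fraction < 1,
            point_spacing > 0, soil_relief_amplitude >= 0,
            length(weed_class_by_quadrat) == 4)
  weed_class_by_quadrat <- match.arg(
    weed_class_by_quadrat, c("none", "grass", "broadleaf", "mixture"),
    several.ok = TRUE)
  structure(as.list(environment())[names(formals(scene_config))],
            class = "scene_config")
}

# class color palettes (mean RGB per class)
.class_colors <- list(maize = c(70, 160, 60),
                      grass = c(90, 170, 70),
                      broadleaf = c(60, 150, 80),
                      soil = c(120, 90, 60),
                      frame = c(250, 250, 250))

# ---- parametric plant construction ---------------------------------------

# Resample a polyline (columns 1:3 xyz, further columns interpolated
# alongside) to roughly uniform arc-length steps of `spacing`.
arc_resample <- function(mat, spacing, min_pts = 3) {
  seg <- sqrt(rowSums((mat[-1, 1:3, drop = FALSE] -
                         mat[-nrow(mat), 1:3, drop = FALSE])^2))
  d <- c(0, cumsum(seg))
  len <- d[length(d)]
  n <- max(min_pts, ceiling(len / spacing) + 1)
  s <- seq(0, len, length.out = n)
  vapply(seq_len(ncol(mat)), function(j)
    stats::approx(d, mat[, j], xout = s)$y, numeric(n))
}

# Closed loft over rings stored ring-major in `v` (nr rings of npr
# points), sealed with apex points at both ends. Faces are wound
# coherently; one global flip guarantees outward orientation (positive
# enclosed volume).
closed_loft <- function(v, nr, npr, apex_start, apex_end) {
  j <- seq_len(npr)
  jn <- c(j[-1], 1L)
  base <- rep((seq_len(nr - 1L) - 1L) * npr, each = npr)
  jj <- rep(j, nr - 1L)
  jjn <- rep(jn, nr - 1L)
  a <- base + jj; b <- base + jjn
  cc <- base + npr + jjn; dd <- base + npr + jj
  a0 <- nr * npr + 1L; a1 <- nr * npr + 2L
  v <- rbind(v, apex_start, apex_end)
  f <- rbind(cbind(a, b, cc), cbind(a, cc, dd),
             cbind(jn, j, a0),
             cbind((nr - 1L) * npr + j, (nr - 1L) * npr + jn, a1))
  dimnames(f) <- NULL
  vol <- signed_volume_raw(v, f)
  if (vol < 0) {
    f <- f[, c(1, 3, 2)]
    vol <- -vol
  }
  list(vertices = v, faces = f, volume = vol)
}

# Thin blade: rectangular cross-section lofted along a centerline, both
# directions sampled at the surface grid spacing.
blade_solid <- function(center, widths, thickness, sidev, spacing) {
  cw <- arc_resample(cbind(center, widths), spacing)
  ctr <- cw[, 1:3, drop = FALSE]
  w <- cw[, 4]
  nr <- nrow(ctr)
  nw <- max(2L, ceiling(max(w) / spacing))
  xs <- seq(-0.5, 0.5, length.out = nw + 1)
  offs_side <- c(xs, rev(xs))
  offs_up <- c(rep(-thickness / 2, nw + 1), rep(thickness / 2, nw + 1))
  npr <- 2L * (nw + 1L)
  rr <- rep(seq_len(nr), each = npr)
  side_coef <- w[rr] * rep(offs_side, nr)
  up_coef <- rep(offs_up, nr)
  v <- ctr[rr, , drop = FALSE] + outer(side_coef, sidev) +
    outer(up_coef, c(0, 0, 1))
  closed_loft(v, nr, npr, ctr[1, ], ctr[nr, ])
}

# Tapered stalk with circular cross-section.
stalk_solid <- function(centers, radii, spacing, apex_start, apex_end) {
  nr <- nrow(centers)
  nseg <- max(8L, ceiling(2 * pi * max(radii) / spacing))
  th <- seq(0, 2 * pi, length.out = nseg + 1)[-(nseg + 1)]
  rr <- rep(seq_len(nr), each = nseg)
  ct <- rep(cos(th), nr)
  st <- rep(sin(th), nr)
  v <- centers[rr, , drop = FALSE] +
    cbind(radii[rr] * ct, radii[rr] * st, 0)
  closed_loft(v, nr, nseg, apex_start, apex_end)
}

unit2 <- function(phi) c(cos(phi), sin(phi), 0)

# Early-stage maize: tapered stalk plus 4-6 arching leaf blades. Every
# closed component carries vertices near the canopy top and no face lies
# entirely below 2 cm, so height-seeded region growth recovers the whole
# plant. The lowest stalk segment is kept tall for the same reason.
build_maize_plant <- function(x, y, base_z, height, spacing) {
  r_base <- runif(1, 0.008, 0.012)
  lean <- rnorm(2, 0, 0.015)
  ztop <- 0.96 * height
  zs <- seq(0.06, ztop, by = spacing)
  if (zs[length(zs)] < ztop) zs <- c(zs, ztop)
  zs <- c(0, zs)
  radii <- r_base * (1 - 0.55 * zs / height)
  centers <- cbind(x + lean[1] * zs, y + lean[2] * zs, base_z + zs)
  stalk <- stalk_solid(centers, radii, spacing,
                       apex_start = c(x, y, base_z + 0.05),
                       apex_end = c(x + lean[1] * height,
                                    y + lean[2] * height,
                                    base_z + height))
  parts <- list(stalk)
  n_leaves <- sample(4:6, 1)
  phi0 <- runif(1, 0, 2 * pi)
  for (l in seq_len(n_leaves)) {
    attach_frac <- runif(1, 0.52, 0.90)
    az <- phi0 + l * pi + rnorm(1, 0, 0.35)
    dirv <- unit2(az)
    sidev <- c(-dirv[2], dirv[1], 0)
    L <- runif(1, 0.13, 0.21)
    rise <- 0.16
    att_z <- base_z + height * attach_frac
    att <- c(x + lean[1] * height * attach_frac + r_base * 0.5 * dirv[1],
             y + lean[2] * height * attach_frac + r_base * 0.5 * dirv[2],
             att_z)
    w0 <- runif(1, 0.028, 0.040)
    tt <- seq(0, 1, length.out = 120)
    center <- cbind(att[1] + dirv[1] * L * tt,
                    att[2] + dirv[2] * L * tt,
                    att_z + rise * sin(0.8 * pi * tt))
    # narrow at the stalk attachment and at the tip, widest mid-blade
    widths <- w0 * sin(pi * (0.15 + 0.7 * tt)) + 0.004
    parts[[length(parts) + 1L]] <-
      blade_solid(center, widths, 0.002, sidev, spacing)
  }
  assemble_plant(parts, base_z + height)
}

assemble_plant <- function(parts, tip_z) {
  list(vertices = do.call(rbind, lapply(parts, `[[`, "vertices")),
       faces = offset_faces(parts),
       volume = sum(vapply(parts, `[[`, numeric(1), "volume")),
       tip_z = tip_z)
}

offset_faces <- function(parts) {
  off <- cumsum(c(0L, vapply(parts, function(p) nrow(p$vertices),
                             integer(1))))
  do.call(rbind, Map(function(p, o) p$faces + o, parts,
                     off[seq_along(parts)]))
}

# Grass weed as a tuft of thin erect blades; the tallest blade reaches the
# nominal plant height.
build_grass_tuft <- function(x, y, base_z, height, spacing) {
  n_blades <- sample(5:9, 1)
  hs <- c(height, height * runif(n_blades - 1, 0.6, 1))
  parts <- vector("list", n_blades)
  tt <- seq(0, 1, length.out = 60)
  for (b in seq_len(n_blades)) {
    bx <- x + runif(1, -0.015, 0.015)
    by <- y + runif(1, -0.015, 0.015)
    dirv <- unit2(runif(1, 0, 2 * pi))
    tiltf <- runif(1, 0.05, 0.25)
    sidev <- c(-dirv[2], dirv[1], 0)
    center <- cbind(bx + dirv[1] * tiltf * hs[b] * tt^1.3,
                    by + dirv[2] * tiltf * hs[b] * tt^1.3,
                    base_z + hs[b] * tt)
    widths <- 0.004 * (1 - 0.6 * tt) + 0.001
    parts[[b]] <- blade_solid(center, widths, 0.0015, sidev, spacing)
  }
  assemble_plant(parts, base_z + height)
}

# Broad-leaved weed as a low rosette of wide short leaves.
build_broadleaf <- function(x, y, base_z, height, spacing) {
  n_leaves <- sample(4:6, 1)
  hs <- c(height, height * runif(n_leaves - 1, 0.5, 0.9))
  phi0 <- runif(1, 0, 2 * pi)
  parts <- vector("list", n_leaves)
  tt <- seq(0, 1, length.out = 60)
  for (l in seq_len(n_leaves)) {
    dirv <- unit2(phi0 + 2 * pi * l / n_leaves + rnorm(1, 0, 0.2))
    sidev <- c(-dirv[2], dirv[1], 0)
    L <- runif(1, 0.03, 0.07)
    center <- cbind(x + dirv[1] * L * tt,
                    y + dirv[2] * L * tt,
                    base_z + hs[l] * tt^0.7)
    widths <- 0.02 * sin(pi * tt) + 0.004
    parts[[l]] <- blade_solid(center, widths, 0.0015, sidev, spacing)
  }
  assemble_plant(parts, base_z + height)
}

# ---- soil and frame ------------------------------------------------------

# smooth random microrelief: sum of seeded cosine waves, scaled to
# +-amplitude
make_relief_fun <- function(amplitude, nwaves = 8) {
  a <- runif(nwaves, 0.3, 1)
  fx <- runif(nwaves, 0.5, 4)
  fy <- runif(nwaves, 0.5, 4)
  ph <- runif(nwaves, 0, 2 * pi)
  scale <- amplitude / sum(a)
  function(x, y) {
    z <- 0
    for (k in seq_len(nwaves))
      z <- z + a[k] * cos(2 * pi * (fx[k] * x + fy[k] * y) + ph[k])
    z * scale
  }
}

grid_mesh <- function(xs, ys, zfun) {
  nx <- length(xs)
  ny <- length(ys)
  g <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  v <- cbind(g$x, g$y, zfun(g$x, g$y))
  i <- rep(seq_len(nx - 1), ny - 1)
  j <- rep(seq_len(ny - 1), each = nx - 1)
  a <- (j - 1) * nx + i
  b <- a + 1L
  c2 <- a + nx
  d <- c2 + 1L
  list(vertices = v, faces = rbind(cbind(a, b, d), cbind(a, d, c2)))
}

build_soil <- function(spacing, relief, extent = c(-0.10, 1.10)) {
  xs <- seq(extent[1], extent[2], by = spacing)
  gm <- grid_mesh(xs, xs, relief)
  # achromatic brightness texture keeps ExG at exactly zero
  tint <- round(runif(nrow(gm$vertices), -10, 10))
  cols <- cbind(.class_colors$soil[1] + tint, .class_colors$soil[2] + tint,
                .class_colors$soil[3] + tint)
  list(vertices = gm$vertices, faces = gm$faces, colors = cols)
}

build_frame_band <- function(spacing, width = 0.03) {
  half <- width / 2
  offs <- seq(-half, half, by = width / 4)
  along <- seq(-half, 1 + half, by = spacing)
  strips <- list(
    grid_mesh(along, offs, function(x, y) 0),       # y = 0 side
    grid_mesh(along, 1 + offs, function(x, y) 0),   # y = 1 side
    grid_mesh(offs, along, function(x, y) 0),       # x = 0 side
    grid_mesh(1 + offs, along, function(x, y) 0))   # x = 1 side
  v <- do.call(rbind, lapply(strips, `[[`, "vertices"))
  f <- offset_faces(lapply(strips, function(s)
    list(vertices = s$vertices, faces = s$faces)))
  cols <- matrix(rep(.class_colors$frame, each = nrow(v)), ncol = 3)
  list(vertices = v, faces = f, colors = cols)
}

# ---- scene generation ----------------------------------------------------

quadrat_bounds <- function(q) {
  # row-major from the frame origin; quadrats 1 and 3 hold the maize row
  xr <- if (q %in% c(1, 3)) c(0, 0.5) else c(0.5, 1)
  yr <- if (q %in% c(1, 2)) c(0, 0.5) else c(0.5, 1)
  list(x = xr, y = yr)
}

place_points <- function(n, xr, yr, min_dist, existing = NULL,
                         max_tries = 400) {
  pts <- matrix(numeric(0), ncol = 2)
  all_pts <- if (is.null(existing)) pts else existing
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- c(runif(1, xr[1], xr[2]), runif(1, yr[1], yr[2]))
      if (nrow(all_pts) == 0 ||
          min(sqrt((all_pts[, 1] - cand[1])^2 +
                     (all_pts[, 2] - cand[2])^2)) >= min_dist) {
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("infeasible packing: too many plants for the quadrat")
    pts <- rbind(pts, cand)
    all_pts <- rbind(all_pts, cand)
  }
  pts
}

#' Generate a synthetic framed field scene with exact ground truth
#'
#' Builds one complete scene — tilled-soil microrelief, white 1 m x 1 m
#' frame band centered on the unit square at z = 0, a maize row through
#' the two row quadrats, and per-quadrat weed cover — with per-face class
#' labels and per-plant enclosed volumes that are exact by construction
#' (each plant is a closed mesh whose volume is computed at build time).
#' All surfaces are tessellated at `config$point_spacing`, emulating the
#' uniform sampling of a fused depth reconstruction. Vertex colors are
#' drawn per class and perturbed with Gaussian channel noise of
#' `config$color_noise_sd`. Identical config and seed reproduce the scene
#' byte for byte.
#'
#' Maize plants are placed so their whole canopy lies inside the frame
#' (as in the field protocol, where the frame is laid around the sampled
#' plants), keeping per-plant ground truth well defined.
#'
#' @param config a [scene_config()].
#' @param mesh build the full scene mesh. With `mesh = FALSE` only the
#'   ground truth is generated (for large statistical replicates); the
#'   same plants are then discretized at a coarser 2 cm step, which
#'   changes stored volumes only by small tessellation differences.
#' @return A `weedvol_scene`: list with `mesh` (or NULL), `frame` (true
#'   [frame_pose()]), `face_labels` (factor per face:
#'   maize/weed/soil/frame), `quadrats` (per-quadrat ground-truth
#'   data.frame), and `plants`.
#' @export
generate_scene <- function(config = scene_config(), mesh = TRUE) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$seed, generate_scene_impl(config, mesh))
}

generate_scene_impl <- function(config, build_mesh) {
  relief <- make_relief_fun(config$soil_relief_amplitude)
  classes <- config$weed_class_by_quadrat
  spacing <- if (build_mesh) config$point_spacing else 0.02

  # maize row at x ~ 0.27 through quadrats 1 and 3
  n1 <- config$n_maize %/% 2
  counts_m <- c(n1, config$n_maize - n1)
  plant_rows <- list()
  centers <- matrix(numeric(0), ncol = 2)
  for (qi in seq_along(c(1, 3))) {
    q <- c(1, 3)[qi]
    nm <- counts_m[qi]
    if (nm == 0) next
    yr <- quadrat_bounds(q)$y
    # keep whole canopies inside the frame: wide margin at the outer
    # frame edge, narrow at the shared midline (truth is per whole plant)
    yin <- if (q == 1) c(yr[1] + 0.26, yr[2] - 0.06)
           else c(yr[1] + 0.06, yr[2] - 0.26)
    ys <- seq(yin[1], yin[2], length.out = max(nm, 1)) +
      runif(nm, -0.015, 0.015)
    xs <- 0.27 + runif(nm, -0.015, 0.015)
    for (i in seq_len(nm)) {
      h <- runif(1, config$maize_height_range[1],
                 config$maize_height_range[2])
      p <- build_maize_plant(xs[i], ys[i], relief(xs[i], ys[i]), h,
                             spacing)
      plant_rows[[length(plant_rows) + 1L]] <-
        list(quadrat = q, class = "maize", x = xs[i], y = ys[i],
             height = p$tip_z, volume = p$volume, part = p)
      centers <- rbind(centers, c(xs[i], ys[i]))
    }
  }

  # weeds per quadrat
  for (q in 1:4) {
    cls <- classes[q]
    if (cls == "none") next
    b <- quadrat_bounds(q)
    xr <- b$x + c(0.05, -0.05)
    yr <- b$y + c(0.05, -0.05)
    nrange <- config$weed_density_range
    spec_list <- switch(cls,
      grass = rep("grass", sample(seq(nrange[1], nrange[2]), 1)),
      broadleaf = rep("broadleaf", sample(seq(nrange[1], nrange[2]), 1)),
      mixture = c(rep("grass",
                      sample(seq(max(1, nrange[1] %/% 2),
                                 max(2, nrange[2] %/% 2)), 1)),
                  rep("broadleaf",
                      sample(seq(max(1, nrange[1] %/% 2),
                                 max(2, nrange[2] %/% 2)), 1))))
    pos <- place_points(length(spec_list), xr, yr, 0.04, centers)
    centers <- rbind(centers, pos)
    for (i in seq_along(spec_list)) {
      sp <- spec_list[i]
      bz <- relief(pos[i, 1], pos[i, 2])
      p <- if (sp == "grass") {
        h <- runif(1, config$grass_height_range[1],
                   config$grass_height_range[2])
        build_grass_tuft(pos[i, 1], pos[i, 2], bz, h, spacing)
      } else {
        h <- runif(1, config$broadleaf_height_range[1],
                   config$broadleaf_height_range[2])
        build_broadleaf(pos[i, 1], pos[i, 2], bz, h, spacing)
      }
      plant_rows[[length(plant_rows) + 1L]] <-
        list(quadrat = q, class = sp, x = pos[i, 1], y = pos[i, 2],
             height = p$tip_z, volume = p$volume, part = p)
    }
  }

  plants <- if (length(plant_rows) == 0)
    data.frame(quadrat = integer(0), class = character(0),
               x = numeric(0), y = numeric(0), height = numeric(0),
               volume = numeric(0))
  else data.frame(
    quadrat = vapply(plant_rows, `[[`, numeric(1), "quadrat"),
    class = vapply(plant_rows, `[[`, character(1), "class"),
    x = vapply(plant_rows, `[[`, numeric(1), "x"),
    y = vapply(plant_rows, `[[`, numeric(1), "y"),
    height = vapply(plant_rows, `[[`, numeric(1), "height"),
    volume = vapply(plant_rows, `[[`, numeric(1), "volume"),
    stringsAsFactors = FALSE)

  frame <- frame_pose(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                            c(0, 1, 0)),
                      normal = c(0, 0, 1), offset = 0, side_length = 1)

  # per-quadrat truth
  qrows <- lapply(1:4, function(q) {
    pq <- plants[plants$quadrat == q, , drop = FALSE]
    weed <- pq[pq$class != "maize", , drop = FALSE]
    wclass <- switch(classes[q], none = "none", grass = "monocots",
                     broadleaf = "dicots", mixture = "mixture")
    wh <- weed_truth_heights(plant_rows, q)
    data.frame(quadrat = q,
               position = if (q %in% c(1, 3)) "row" else "inter_row",
               weed_class = wclass,
               maize_count = sum(pq$class == "maize"),
               weed_density = nrow(weed),
               true_maize_volume = sum(pq$volume[pq$class == "maize"]),
               true_weed_volume = sum(weed$volume),
               weed_max_height_m = wh[1], weed_p90_height_m = wh[2],
               weed_mean_height_m = wh[3],
               stringsAsFactors = FALSE)
  })
  quadrats <- do.call(rbind, qrows)
  # standalone biomass draw (studies recalibrate this against a target r)
  eps_m <- rnorm(4, 0, config$biomass_cv)
  eps_w <- rnorm(4, 0, config$biomass_cv)
  quadrats$eps_maize <- ifelse(quadrats$true_maize_volume > 0, eps_m, 0)
  quadrats$eps_weed <- ifelse(quadrats$true_weed_volume > 0, eps_w, 0)
  quadrats$maize_biomass_g <- config$maize_density_factor *
    quadrats$true_maize_volume * (1 + quadrats$eps_maize)
  quadrats$weed_biomass_g <- config$weed_density_factor *
    quadrats$true_weed_volume * (1 + quadrats$eps_weed)

  scene <- list(mesh = NULL, frame = frame, face_labels = NULL,
                quadrats = quadrats, plants = plants, config = config)
  class(scene) <- "weedvol_scene"
  if (!build_mesh) return(scene)

  soil <- build_soil(config$point_spacing, relief)
  band <- build_frame_band(config$point_spacing)
  parts_geo <- c(list(soil, band), lapply(plant_rows, function(pr)
    list(vertices = pr$part$vertices, faces = pr$part$faces,
         colors = matrix(rep(.class_colors[[pr$class]],
                             each = nrow(pr$part$vertices)), ncol = 3))))
  labels_per_part <- c("soil", "frame",
                       ifelse(plants$class == "maize", "maize", "weed"))
  v <- do.call(rbind, lapply(parts_geo, `[[`, "vertices"))
  f <- offset_faces(parts_geo)
  cols <- do.call(rbind, lapply(parts_geo, `[[`, "colors"))
  if (config$color_noise_sd > 0) {
    cols <- cols + matrix(rnorm(length(cols), 0, config$color_noise_sd),
                          ncol = 3)
  }
  cols <- round(pmin(pmax(cols, 0), 255))
  face_counts <- vapply(parts_geo, function(p) nrow(p$faces), integer(1))
  scene$face_labels <- factor(rep(labels_per_part, face_counts),
                              levels = c("maize", "weed", "soil", "frame"))
  scene$mesh <- trimesh(v, f, cols)
  scene
}

weed_truth_heights <- function(plant_rows, q) {
  zs <- unlist(lapply(plant_rows, function(pr) {
    if (pr$quadrat == q && pr$class != "maize") pr$part$vertices[, 3]
    else NULL
  }))
  if (is.null(zs) || length(zs) == 0) return(c(NA_real_, NA_real_,
                                               NA_real_))
  c(max(zs), as.numeric(quantile(zs, 0.9, names = FALSE)), mean(zs))
}

#' @export
print.weedvol_scene <- function(x, ...) {
  cat(sprintf("<weedvol_scene> %s, %d plants, %d quadrats\n",
              if (is.null(x$mesh)) "truth only"
              else sprintf("%d faces", n_faces(x$mesh)),
              nrow(x$plants), nrow(x$quadrats)))
  invisible(x)
}

# ---- study generation ----------------------------------------------------

#' Generate a full synthetic study (40 quadrats by default)
#'
#' Emulates the field campaign layout: `n_scenes` framed scenes of four
#' quadrats each, half of the quadrats on the maize row and half
#' inter-row, with a fixed mix of weed-free, grass-only, broadleaf-only,
#' and mixed quadrats shuffled over the study. Dry biomass is generated as
#' `biomass = a * volume * (1 + eps)` with `eps ~ Normal(0, sigma)`, sigma
#' calibrated from the realized volume moments so that the population
#' correlation between volume and biomass equals `target_r` (sigma = 0
#' when `target_r = 1`).
#'
#' @param n_scenes number of 1 m x 1 m frames (4 quadrats each).
#' @param target_r requested population correlation between volume and
#'   biomass, per class.
#' @param composition named integer vector distributing the quadrats over
#'   weed cover types; must sum to `4 * n_scenes`.
#' @param scene_opts list of overrides passed to [scene_config()].
#' @param meshes build full scene meshes (`FALSE` keeps only ground
#'   truth, for large statistical replicates).
#' @param seed study seed.
#' @return List with `scenes` (list of `weedvol_scene`) and `truth` (one
#'   row per quadrat; `sample_id` is `S<scene>_Q<quadrat>`).
#' @export
generate_study <- function(n_scenes = 10, target_r = 0.85,
                           composition = c(grass = 12, broadleaf = 10,
                                           mixture = 10, none = 8),
                           scene_opts = list(), meshes = TRUE, seed = 1) {
  nq <- 4 * n_scenes
  if (sum(composition) != nq)
    stop("composition must sum to 4 * n_scenes")
  stopifnot(target_r > 0, target_r <= 1)
  with_seed(seed, {
    classes <- sample(rep(names(composition), composition))
    scene_seeds <- sample.int(.Machine$integer.max, n_scenes)
    scenes <- vector("list", n_scenes)
    truths <- vector("list", n_scenes)
    for (i in seq_len(n_scenes)) {
      opts <- scene_opts
      opts$weed_class_by_quadrat <- classes[4 * (i - 1) + 1:4]
      opts$seed <- scene_seeds[i]
      if (is.null(opts$n_maize)) opts$n_maize <- sample(4:6, 1)
      cfg <- do.call(scene_config, opts)
      sc <- generate_scene(cfg, mesh = meshes)
      scenes[[i]] <- sc
      tr <- sc$quadrats
      tr$scene <- i
      tr$sample_id <- sprintf("S%02d_Q%d", i, tr$quadrat)
      truths[[i]] <- tr
    }
    truth <- do.call(rbind, truths)
    # recalibrate biomass noise against the requested population r
    cfg0 <- do.call(scene_config,
                    c(scene_opts[setdiff(names(scene_opts),
                                         c("seed",
                                           "weed_class_by_quadrat"))],
                      list(seed = 1L)))
    truth$eps_maize <- calibrated_eps(truth$true_maize_volume, target_r)
    truth$eps_weed <- calibrated_eps(truth$true_weed_volume, target_r)
    truth$maize_biomass_g <- cfg0$maize_density_factor *
      truth$true_maize_volume * (1 + truth$eps_maize)
    truth$weed_biomass_g <- cfg0$weed_density_factor *
      truth$true_weed_volume * (1 + truth$eps_weed)
    rownames(truth) <- NULL
    list(scenes = scenes, truth = truth, target_r = target_r,
         seed = seed)
  })
}

# sigma such that cor(V, a V (1+eps)) = r for eps ~ N(0, sigma^2)
# independent of V:  sigma^2 = Var(V) (1/r^2 - 1) / E(V^2)
calibrated_eps <- function(v, target_r) {
  if (target_r >= 1) return(rep(0, length(v)))
  vv <- var(v) * (length(v) - 1) / length(v)
  m2 <- mean(v^2)
  if (m2 == 0 || vv == 0) return(rep(0, length(v)))
  sigma <- sqrt(vv * (1 / target_r^2 - 1) / m2)
  ifelse(v > 0, rnorm(length(v), 0, sigma), 0)
}

# ---- sensor noise --------------------------------------------------------

# smooth random depth-error field with the requested standard deviation
# (random-phase cosines, wavelengths ~8-50 cm)
make_noise_field <- function(sd_target, nwaves = 12) {
  a <- runif(nwaves, 0.3, 1)
  fx <- runif(nwaves, 2, 12)
  fy <- runif(nwaves, 2, 12)
  ph <- runif(nwaves, 0, 2 * pi)
  a <- a * sd_target * sqrt(2 / sum(a^2))
  function(x, y) {
    z <- 0
    for (k in seq_len(nwaves))
      z <- z + a[k] * cos(2 * pi * (fx[k] * x + fy[k] * y) + ph[k])
    z
  }
}

#' Add depth-camera sensor artifacts to a scene mesh
#'
#' Perturbs vertex positions along the view axis (vertical, for a
#' top-view acquisition), drops a fraction of faces (dropout), and
#' injects isolated outlier points at least 2 cm away from any surface
#' vertex — the artifacts the isolated-point filter is designed to
#' remove. The depth error is modeled as frame-fusion residue: a smooth
#' random field of the requested standard deviation (low-frequency
#' registration error, the dominant error of ICP-fused multi-frame
#' reconstructions) plus a small white per-vertex residual (0.3 mm), the
#' speckle left after fusion averaging. All-zero settings return the
#' input unchanged; a given seed reproduces the output exactly.
#'
#' @param mesh a [trimesh()].
#' @param depth_noise_sd total depth error sd (m).
#' @param outlier_fraction injected outliers as a fraction of the vertex
#'   count.
#' @param dropout_fraction fraction of faces removed.
#' @param seed optional RNG seed.
#' @return A [trimesh()] with attributes `outlier_vertices` (indices of
#'   injected points) and `orig_faces`.
#' @export
add_sensor_noise <- function(mesh, depth_noise_sd = 0.003,
                             outlier_fraction = 0.01,
                             dropout_fraction = 0.002, seed = NULL) {
  run <- function() {
    v <- mesh$vertices
    cols <- mesh$vertex_colors
    nf <- n_faces(mesh)
    f <- mesh$faces
    kept_faces <- seq_len(nf)
    if (depth_noise_sd > 0) {
      field <- make_noise_field(depth_noise_sd)
      v[, 3] <- v[, 3] + field(v[, 1], v[, 2]) +
        rnorm(nrow(v), 0, 3e-4)
    }
    if (dropout_fraction > 0 && nf > 0) {
      ndrop <- round(dropout_fraction * nf)
      if (ndrop > 0) {
        drop <- sample.int(nf, ndrop)
        kept_faces <- setdiff(kept_faces, drop)
        f <- f[kept_faces, , drop = FALSE]
      }
    }
    n_out <- round(outlier_fraction * nrow(v))
    out_idx <- integer(0)
    if (n_out > 0) {
      lo <- apply(v, 2, min)
      hi <- apply(v, 2, max)
      accepted <- matrix(numeric(0), ncol = 3)
      guard <- 0
      while (nrow(accepted) < n_out && guard < 50) {
        guard <- guard + 1
        cand <- cbind(runif(2 * n_out, lo[1], hi[1]),
                      runif(2 * n_out, lo[2], hi[2]),
                      runif(2 * n_out, lo[3], hi[3] + 0.3))
        ok <- cross_neighbor_counts(cand, v, 0.02) == 0
        accepted <- rbind(accepted, cand[ok, , drop = FALSE])
      }
      if (nrow(accepted) < n_out)
        stop("could not place outliers clear of the surface")
      accepted <- accepted[seq_len(n_out), , drop = FALSE]
      out_idx <- nrow(v) + seq_len(n_out)
      v <- rbind(v, accepted)
      if (!is.null(cols))
        cols <- rbind(cols, matrix(rep(c(128L, 128L, 128L),
                                       each = n_out), ncol = 3))
    }
    out <- trimesh(v, f, cols)
    parent <- attr(mesh, "orig_faces")
    attr(out, "orig_faces") <-
      if (is.null(parent)) kept_faces else parent[kept_faces]
    attr(out, "outlier_vertices") <- out_idx
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# ---- feature-level experiment -------------------------------------------

#' Simulate per-quadrat weed height features for classification
#'
#' Draws the weed-height feature set used to probe the canonical
#' discriminant classifier under the study's measured height separations:
#' grass-infested samples with maximum weed height uniform on
#' `grass_range`, broadleaf-only samples uniform on `broadleaf_range`,
#' and mixtures whose maximum equals a grass draw (the tallest plant in a
#' mixed sample is a grass). The 90th-percentile height is
#' `p90_factor * max`.
#'
#' @param n_grass,n_broadleaf,n_mixture samples per group.
#' @param grass_range,broadleaf_range max-height ranges (m).
#' @param p90_factor ratio of 90th-percentile to maximum height.
#' @param seed optional RNG seed.
#' @return data.frame with `weed_class` (monocots/dicots/mixture),
#'   `max_height`, `p90_height`.
#' @export
simulate_height_features <- function(n_grass = 13, n_broadleaf = 13,
                                     n_mixture = 10,
                                     grass_range = c(0.12, 0.20),
                                     broadleaf_range = c(0.02, 0.10),
                                     p90_factor = 0.9, seed = NULL) {
  run <- function() {
    mx <- c(runif(n_grass, grass_range[1], grass_range[2]),
            runif(n_broadleaf, broadleaf_range[1], broadleaf_range[2]),
            runif(n_mixture, grass_range[1], grass_range[2]))
    data.frame(
      weed_class = factor(rep(c("monocots", "dicots", "mixture"),
                              c(n_grass, n_broadleaf, n_mixture)),
                          levels = c("monocots", "dicots", "mixture")),
      max_height = mx,
      p90_height = p90_factor * mx)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
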
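test_that("signed_volume reproduces closed forms", {
  expect_equal(as.numeric(signed_volume(make_cube_mesh())), 1.0)
  expect_equal(as.numeric(signed_volume(make_tetra_mesh())), 1 / 6)
  expect_equal(as.numeric(signed_volume(icosahedron_mesh())),
               icosahedron_volume(), tolerance = 1e-12)
})

test_that("signed_volume matches the closed-form oracle on random convex meshes", {
  set.seed(13)
  base <- icosahedron_mesh()
  v0 <- icosahedron_volume()
  for (i in 1:20) {
    A <- matrix(rnorm(9, sd = 0.12), 3, 3) + diag(0.12, 3)
    while (abs(det(A)) < 1e-4) A <- matrix(rnorm(9, sd = 0.12), 3, 3)
    m <- base
    m$vertices <- base$vertices %*% t(A) + matrix(runif(3), 12, 3,
                                                  byrow = TRUE)
    expect_equal(as.numeric(signed_volume(m)), v0 * abs(det(A)),
                 tolerance = 1e-12)
  }
})

test_that("signed_volume is invariant to rigid motion and input winding", {
  set.seed(2)
  m <- icosphere_mesh(2, r = 0.3)
  v <- as.numeric(signed_volume(m))
  mt <- m
  mt$vertices <- sweep(m$vertices %*% random_rotation(), 2,
                       runif(3, -5, 5), "+")
  expect_equal(as.numeric(signed_volume(mt)), v, tolerance = 1e-12)
  # scramble windings: orientation repair must recover the same volume
  ms <- m
  flip <- sample(c(TRUE, FALSE), nrow(m$faces), TRUE)
  ms$faces[flip, ] <- ms$faces[flip, c(1, 3, 2)]
  expect_equal(as.numeric(signed_volume(ms)), v, tolerance = 1e-12)
  # scaling law
  m8 <- m
  m8$vertices <- m$vertices * 2
  expect_equal(as.numeric(signed_volume(m8)), 8 * v, tolerance = 1e-12)
})

test_that("an open mesh raises a watertightness error", {
  m <- make_cube_mesh()
  m$faces <- m$faces[-1, ]
  expect_error(signed_volume(m), "not watertight")
  expect_error(voxel_volume(m), "not watertight")
})

test_that("close_to_ground seals a hemisphere to its closed-form volume", {
  gp <- list(normal = c(0, 0, 1), offset = 0)
  r <- 0.1
  coarse <- close_to_ground(hemisphere_mesh(r, 12, 24), gp)
  fine <- close_to_ground(hemisphere_mesh(r, 48, 96), gp)
  vtrue <- 2 / 3 * pi * r^3
  err_c <- abs(as.numeric(signed_volume(coarse)) - vtrue)
  err_f <- abs(as.numeric(signed_volume(fine)) - vtrue)
  expect_lt(err_f, err_c)                     # refinement converges
  expect_equal(as.numeric(signed_volume(fine)), vtrue, tolerance = 0.005)
})

test_that("close_to_ground returns a closed mesh unchanged", {
  gp <- list(normal = c(0, 0, 1), offset = 0)
  m <- make_cube_mesh()
  expect_identical(close_to_ground(m, gp), m)
})

test_that("closing a plant opened at the base recovers its volume within 2%", {
  set.seed(77)
  p <- weedvol:::build_maize_plant(0.3, 0.3, 0, 0.5, 0.007)
  m <- trimesh(p$vertices, p$faces)
  # remove the stalk base cap (faces entirely below 6 cm) -> open canopy
  zmax <- apply(matrix(m$vertices[t(m$faces), 3], nrow = 3), 2, max)
  open_mesh <- submesh(m, zmax > 0.06)
  expect_false(is_watertight(open_mesh))
  closed <- close_to_ground(open_mesh, list(normal = c(0, 0, 1),
                                            offset = 0))
  expect_true(is_watertight(closed))
  expect_equal(as.numeric(signed_volume(closed)), p$volume,
               tolerance = 0.02)
})

test_that("pieces of a cut plant sum to the whole volume", {
  set.seed(78)
  p <- weedvol:::build_maize_plant(0, 0, 0, 0.45, 0.01)
  m <- trimesh(p$vertices, p$faces)
  gp <- list(normal = c(0, 0, 1), offset = 0)
  cent <- weedvol:::face_centroids(m)
  for (cut in c(0.05, 0.12)) {
    a <- close_to_ground(submesh(m, cent[, 1] < cut), gp)
    b <- close_to_ground(submesh(m, cent[, 1] >= cut), gp)
    expect_equal(as.numeric(signed_volume(a)) +
                   as.numeric(signed_volume(b)),
                 p$volume, tolerance = 1e-9)
  }
})

test_that("prism_volume handles flat, tilted, and random height fields", {
  gp <- list(normal = c(0, 0, 1), offset = 0)
  sheet <- function(zfun, n = 40) {
    gm <- weedvol:::grid_mesh(seq(0, 1, length.out = n),
                              seq(0, 1, length.out = n), zfun)
    trimesh(gm$vertices, gm$faces)
  }
  expect_equal(prism_volume(sheet(function(x, y) 0.1), gp), 0.1,
               tolerance = 1e-12)
  expect_equal(prism_volume(sheet(function(x, y) 0.2 * x), gp), 0.1,
               tolerance = 1e-12)
  # random smooth height field vs fine-raster integration oracle
  zf <- function(x, y) 0.05 + 0.02 * sin(2 * pi * x) * cos(2 * pi * y) +
    0.01 * x * y
  est <- prism_volume(sheet(zf, 80), gp)
  g <- seq(0.0005, 0.9995, by = 0.001)
  oracle <- mean(outer(g, g, zf))
  expect_equal(est, oracle, tolerance = 0.005)
})

test_that("voxel volume approximates closed forms and converges", {
  cube <- make_cube_mesh()
  expect_equal(voxel_volume(cube, 0.01), 1, tolerance = 0.03)
  sph <- icosphere_mesh(3, r = 0.1)
  vs <- as.numeric(signed_volume(sph))
  expect_equal(voxel_volume(sph, 0.005), 4 / 3 * pi * 0.1^3,
               tolerance = 0.03)
  set.seed(4)
  for (i in 1:5) {
    A <- matrix(rnorm(9, sd = 0.05), 3, 3) + diag(0.05, 3)
    hull <- icosahedron_mesh()
    hull$vertices <- hull$vertices %*% t(A)
    ref <- as.numeric(signed_volume(hull))
    errs <- vapply(c(0.02, 0.01, 0.005), function(h)
      abs(voxel_volume(hull, h) - ref), numeric(1))
    # refinement improves agreement overall; single halving steps can
    # fluctuate within lattice-counting noise
    expect_lt(errs[3], errs[1])
    expect_lt(errs[3] / ref, 5e-4)
  }
})

test_that("quadrat_volume_report composes segmentation and closure", {
  # soil-and-frame-only scene: every volume is exactly zero
  sc0 <- generate_scene(scene_config(seed = 61, n_maize = 0,
                                     weed_class_by_quadrat = rep("none", 4),
                                     color_noise_sd = 0))
  fr0 <- detect_frame(sc0$mesh)
  q0 <- split_quadrats(crop_to_frame(sc0$mesh, fr0), fr0)[[1]]
  vr0 <- quadrat_volume_report(segment_sample(q0), fr0$ground_plane)
  expect_equal(vr0$maize_volume, 0)
  expect_equal(vr0$weed_volume, 0)
  expect_equal(vr0$total_volume, 0)

  # weedy quadrat: total bounds each part
  sc <- generate_scene(scene_config(seed = 61, color_noise_sd = 0))
  fr <- detect_frame(sc$mesh)
  quads <- split_quadrats(crop_to_frame(sc$mesh, fr), fr)
  seg <- segment_sample(quads[[2]])
  vr <- quadrat_volume_report(seg, fr$ground_plane)
  expect_gte(vr$total_volume, vr$weed_volume - 1e-12)
  expect_gte(vr$total_volume, vr$maize_volume - 1e-12)

  # doubling all coordinates multiplies every volume by 8 (closed plants,
  # so the result does not depend on closure heuristics)
  set.seed(62)
  mz <- weedvol:::build_maize_plant(0.2, 0.2, 0, 0.5, 0.01)
  wd <- weedvol:::build_grass_tuft(0.6, 0.6, 0, 0.15, 0.01)
  seg_c <- structure(list(maize_mesh = trimesh(mz$vertices, mz$faces),
                          weed_mesh = trimesh(wd$vertices, wd$faces),
                          soil_mesh = trimesh(matrix(numeric(0), ncol = 3),
                                              NULL)),
                     class = "segmentation_result")
  gp <- list(normal = c(0, 0, 1), offset = 0)
  vr1 <- quadrat_volume_report(seg_c, gp)
  expect_equal(vr1$maize_volume, mz$volume, tolerance = 1e-12)
  seg_d <- seg_c
  seg_d$maize_mesh$vertices <- seg_d$maize_mesh$vertices * 2
  seg_d$weed_mesh$vertices <- seg_d$weed_mesh$vertices * 2
  vr8 <- quadrat_volume_report(seg_d, gp)
  expect_equal(vr8$maize_volume, 8 * vr1$maize_volume, tolerance = 1e-12)
  expect_equal(vr8$weed_volume, 8 * vr1$weed_volume, tolerance = 1e-12)
  expect_equal(vr8$total_volume, 8 * vr1$total_volume, tolerance = 1e-12)
})
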
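test_that("trimesh validates faces and colors", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_error(trimesh(v, rbind(c(1, 2, 100))), "face 1.*100")
  expect_error(trimesh(v, rbind(c(1, 2, 2))), "repeats a vertex")
  expect_error(trimesh(v, rbind(c(1, 2, 3)),
                       vertex_colors = rbind(c(0, 0, 0))),
               "one row per vertex")
  expect_error(trimesh(rbind(c(0, 0, NA)), NULL), "finite")
})

test_that("PLY round trip preserves geometry and colors in both dialects", {
  m <- small_colored_mesh()
  for (binary in c(FALSE, TRUE)) {
    path <- withr::local_tempfile(fileext = ".ply")
    write_mesh(m, path, binary = binary)
    back <- read_mesh(path)
    expect_equal(back$vertices, m$vertices, tolerance = 1e-6)
    expect_identical(back$faces, m$faces)
    expect_identical(back$vertex_colors, m$vertex_colors)
  }
})

test_that("ASCII and binary PLY of the same mesh read back equal", {
  set.seed(11)
  for (i in 1:5) {
    m <- trimesh(matrix(runif(30), ncol = 3),
                 t(replicate(6, sample.int(10, 3))),
                 matrix(sample(0:255, 30, TRUE), ncol = 3))
    pa <- withr::local_tempfile(fileext = ".ply")
    pb <- withr::local_tempfile(fileext = ".ply")
    write_mesh(m, pa, binary = FALSE)
    write_mesh(m, pb, binary = TRUE)
    a <- read_mesh(pa)
    b <- read_mesh(pb)
    expect_equal(a$vertices, b$vertices, tolerance = 1e-6)
    expect_identical(a$faces, b$faces)
    expect_identical(a$vertex_colors, b$vertex_colors)
  }
})

test_that("PLY writes are byte-stable for fixed input", {
  set.seed(3)
  for (i in 1:10) {
    m <- trimesh(matrix(runif(30), ncol = 3),
                 t(replicate(5, sample.int(10, 3))))
    p1 <- withr::local_tempfile(fileext = ".ply")
    p2 <- withr::local_tempfile(fileext = ".ply")
    write_mesh(m, p1, binary = i %% 2 == 0)
    write_mesh(m, p2, binary = i %% 2 == 0)
    expect_identical(readBin(p1, "raw", file.size(p1)),
                     readBin(p2, "raw", file.size(p2)))
  }
})

test_that("PLY with an out-of-range face index is rejected", {
  path <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 4",
               "property float x", "property float y",
               "property float z", "element face 1",
               "property list uchar int vertex_indices", "end_header",
               "0 0 0", "1 0 0", "0 1 0", "0 0 1", "3 0 1 99"), path)
  expect_error(read_mesh(path), "face 1.*100|references vertex")
})

test_that("OBJ writes geometry and reads it back", {
  m <- make_tetra_mesh()
  path <- withr::local_tempfile(fileext = ".obj")
  write_mesh(m, path)
  back <- read_mesh(path)
  expect_equal(back$vertices, m$vertices, tolerance = 1e-9)
  expect_identical(back$faces, m$faces)
})

test_that("missing files raise an I/O error", {
  expect_error(read_mesh("no/such/file.ply"), "no such file")
})

test_that("connected_components handles trivial topologies", {
  two <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                       c(5, 5, 5), c(6, 5, 5), c(5, 6, 5)),
                 rbind(c(1, 2, 3), c(4, 5, 6)))
  lab <- connected_components(two)
  expect_equal(lab$n_components, 2L)
  expect_false(lab$face_labels[1] == lab$face_labels[2])

  cube <- make_cube_mesh()
  expect_equal(connected_components(cube)$n_components, 1L)

  empty <- trimesh(matrix(numeric(0), ncol = 3), NULL)
  lab0 <- connected_components(empty)
  expect_equal(lab0$n_components, 0L)
  expect_length(lab0$face_labels, 0L)
})

test_that("connected_components agrees with an igraph oracle on random clusters", {
  skip_if_not_installed("igraph")
  set.seed(21)
  parts <- lapply(1:50, function(k) {
    ic <- icosphere_mesh(sample(0:1, 1), r = 0.05)
    ic$vertices <- sweep(ic$vertices, 2, runif(3, -5, 5), "+")
    ic
  })
  m <- merge_meshes(parts)
  lab <- connected_components(m)
  # oracle: graph over faces sharing an edge, via igraph components
  ek <- weedvol:::face_edge_keys(m)
  df <- data.frame(key = as.vector(ek),
                   face = rep(seq_len(nrow(m$faces)), 3))
  sp <- split(df$face, df$key)
  pairs <- do.call(rbind, lapply(sp[lengths(sp) > 1], function(fs)
    cbind(fs[-length(fs)], fs[-1])))
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(m$faces) - igraph::vcount(g))
  oracle <- igraph::components(g)$membership
  expect_equal(lab$n_components, 50L)
  # identical partitions (up to label names)
  expect_equal(length(unique(paste(lab$face_labels, oracle))),
               lab$n_components)
})

test_that("component ids are ordered by descending face count", {
  big <- icosphere_mesh(1, r = 1)                      # 80 faces
  small <- make_tetra_mesh()                           # 4 faces
  small$vertices <- small$vertices + 10
  m <- merge_meshes(list(small, big))
  lab <- connected_components(m)
  expect_equal(lab$face_labels[1], 2L)             # tetra listed second
  expect_equal(lab$face_labels[5], 1L)             # sphere is component 1
})

test_that("clean_mesh removes degenerate faces and is idempotent", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(0, 1, 0))
  m <- trimesh(v, rbind(c(1, 2, 3), c(1, 2, 4)))  # first face collinear
  cl <- clean_mesh(m)
  expect_equal(nrow(cl$faces), 1L)
  expect_equal(nrow(cl$vertices), 3L)  # unreferenced vertex dropped
  expect_equal(clean_mesh(cl), cl)

  good <- make_cube_mesh()
  expect_equal(clean_mesh(good)$vertices, good$vertices)
  expect_equal(nrow(clean_mesh(good)$faces), 12L)
})

test_that("clean_mesh face count matches a direct area-threshold count", {
  set.seed(9)
  base <- icosphere_mesh(1, r = 0.3)
  nv <- nrow(base$vertices)
  # inject degenerate faces: repeated-position triangles (zero area)
  extra_v <- base$vertices[sample(nv, 6), ]
  v <- rbind(base$vertices, extra_v, extra_v + 1e-15)
  dg <- cbind(nv + 1:6, nv + 6 + 1:6, sample(nv, 6))
  m <- trimesh(v, rbind(base$faces, dg))
  areas <- weedvol:::face_areas(m)
  expect_equal(nrow(clean_mesh(m)$faces), sum(areas >= 1e-12))
  expect_equal(nrow(clean_mesh(m)$faces), nrow(base$faces))
})

test_that("submesh composes orig_faces through repeated subsetting", {
  m <- merge_meshes(list(make_tetra_mesh(), make_cube_mesh()))
  s1 <- submesh(m, 3:14)
  s2 <- submesh(s1, c(1, 5))
  expect_equal(attr(s2, "orig_faces"), c(3L, 7L))
})
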
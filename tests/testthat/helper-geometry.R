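# Shared geometric fixtures, all built in code.

make_cube_mesh <- function(side = 1, origin = c(0, 0, 0)) {
  g <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  v <- sweep(g * side, 2, origin, "+")
  # 12 triangles over the 6 faces (outward orientation not required;
  # signed_volume repairs it)
  f <- rbind(c(1, 3, 4), c(1, 4, 2),
             c(5, 6, 8), c(5, 8, 7),
             c(1, 2, 6), c(1, 6, 5),
             c(3, 7, 8), c(3, 8, 4),
             c(1, 5, 7), c(1, 7, 3),
             c(2, 4, 8), c(2, 8, 6))
  trimesh(v, f)
}

make_tetra_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  trimesh(v, f)
}

# regular icosahedron with edge length 2: closed-form volume
# 5 (3 + sqrt(5)) / 12 * a^3
icosahedron_mesh <- function() {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11),
             c(1, 11, 12), c(2, 6, 10), c(6, 12, 5), c(12, 11, 3),
             c(11, 8, 7), c(8, 2, 9), c(4, 10, 5), c(4, 5, 3),
             c(4, 3, 7), c(4, 7, 9), c(4, 9, 10), c(5, 10, 6),
             c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  trimesh(v, f)
}

icosahedron_volume <- function() 5 * (3 + sqrt(5)) / 12 * 8

# geodesic sphere by midpoint subdivision of the icosahedron
icosphere_mesh <- function(level, r = 1) {
  ic <- icosahedron_mesh()
  v <- ic$vertices / sqrt(rowSums(ic$vertices^2))
  f <- ic$faces
  for (l in seq_len(level)) {
    env <- new.env(parent = emptyenv())
    mid <- function(a, b) {
      k <- paste(min(a, b), max(a, b))
      got <- env[[k]]
      if (!is.null(got)) return(got)
      p <- v[a, ] + v[b, ]
      p <- p / sqrt(sum(p^2))
      v <<- rbind(v, p)
      env[[k]] <- nrow(v)
      nrow(v)
    }
    nf <- vector("list", nrow(f))
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c3 <- f[i, 3]
      ab <- mid(a, b); bc <- mid(b, c3); ca <- mid(c3, a)
      nf[[i]] <- rbind(c(a, ab, ca), c(b, bc, ab), c(c3, ca, bc),
                       c(ab, bc, ca))
    }
    f <- do.call(rbind, nf)
  }
  trimesh(v * r, f)
}

# open upper hemisphere (lat-long grid), boundary at the equator
hemisphere_mesh <- function(r = 0.1, nlat = 24, nlon = 48) {
  lat <- seq(0, pi / 2 - 1e-9, length.out = nlat) # 0 = equator
  lon <- seq(0, 2 * pi, length.out = nlon + 1)[-(nlon + 1)]
  v <- do.call(rbind, lapply(lat, function(la)
    cbind(r * cos(la) * cos(lon), r * cos(la) * sin(lon),
          r * sin(la))))
  apex <- nrow(v) + 1L
  v <- rbind(v, c(0, 0, r))
  j <- seq_len(nlon)
  jn <- c(j[-1], 1L)
  f <- do.call(rbind, lapply(seq_len(nlat - 1), function(i) {
    a <- (i - 1) * nlon + j
    b <- (i - 1) * nlon + jn
    rbind(cbind(a, b, b + nlon), cbind(a, b + nlon, a + nlon))
  }))
  top <- (nlat - 1) * nlon
  f <- rbind(f, cbind(top + j, top + jn, apex))
  trimesh(v, f)
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
        c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
        c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

# ray-casting point-in-polygon (2D), the classic even-odd rule
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- (yi > py) != (yj > py)
    xint <- (xj - xi) * (py - yi) / (yj - yi) + xi
    inside <- xor(inside, cross & (px < xint))
    j <- i
  }
  inside
}

# per-class precision/recall of a predicted face labeling
face_precision_recall <- function(pred, truth, class) {
  tp <- sum(pred == class & truth == class)
  c(precision = tp / max(sum(pred == class), 1),
    recall = tp / max(sum(truth == class), 1))
}

# small colored two-triangle mesh for I/O round trips
small_colored_mesh <- function() {
  trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0.5)),
          rbind(c(1, 2, 3), c(2, 4, 3)),
          rbind(c(255, 0, 0), c(0, 255, 0), c(0, 0, 255),
                c(128, 128, 128)))
}
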
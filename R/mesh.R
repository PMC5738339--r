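# Triangle mesh container and synthetic spherical meshes.

#' Construct a triangle mesh
#'
#' A minimal container for a triangulated surface: vertex coordinates in mm
#' and triangle faces. Faces are stored 1-based (R convention); all file
#' formats use 0-based indices and are converted at the I/O boundary.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z (mm).
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param name free-text mesh identifier.
#' @return an object of class `lsctp_mesh` with elements `vertices`, `faces`,
#'   `name`.
#' @export
triangle_mesh <- function(vertices, faces, name = "mesh") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) {
    lsctp_abort("vertices must have 3 coordinate columns", "lsctp_dimension_error")
  }
  if (ncol(faces) != 3L) {
    lsctp_abort("faces must have 3 vertex columns", "lsctp_dimension_error")
  }
  nv <- nrow(vertices)
  if (nrow(faces) > 0L) {
    if (any(faces < 1L) || any(faces > nv)) {
      lsctp_abort("face indices out of range", "lsctp_bounds_error")
    }
    if (any(faces[, 1L] == faces[, 2L] | faces[, 2L] == faces[, 3L] |
              faces[, 1L] == faces[, 3L])) {
      lsctp_abort("degenerate face repeats a vertex", "lsctp_invariant_error")
    }
  }
  structure(
    list(vertices = vertices, faces = faces, name = as.character(name)),
    class = "lsctp_mesh"
  )
}

#' @export
print.lsctp_mesh <- function(x, ...) {
  cat(sprintf(
    "<lsctp_mesh '%s': %d vertices, %d faces>\n",
    x$name, nrow(x$vertices), nrow(x$faces)
  ))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)

#' Subdivided icosahedral sphere
#'
#' Builds an icosahedron, applies `subdivisions` rounds of 4-way triangle
#' subdivision (new vertices at edge midpoints, deduplicated), and projects
#' every vertex onto a sphere of the requested radius. Vertex count is
#' `10 * 4^subdivisions + 2`. These meshes stand in for the registration
#' sphere on which windowing is performed: near-uniform vertex density, so
#' windows of a fixed diameter hold near-identical vertex counts everywhere.
#'
#' @param subdivisions non-negative integer; 0 gives the icosahedron.
#' @param radius sphere radius in mm. The default of 15.2 mm gives a
#'   subdivision-4 mesh a mean inter-neighbor distance close to 1 mm,
#'   matching the vertex density of full-resolution registration spheres.
#' @return an `lsctp_mesh`.
#' @export
make_icosphere <- function(subdivisions = 4L, radius = 15.2) {
  if (subdivisions < 0L) lsctp_abort("subdivisions must be >= 0", "lsctp_parameter_error")
  if (radius <= 0) lsctp_abort("radius must be > 0", "lsctp_parameter_error")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    # undirected edge keys; doubles hold these products exactly (< 2^53)
    pair_key <- function(a, b) pmin(a, b) * (nv + 1) + pmax(a, b)
    k12 <- pair_key(f[, 1], f[, 2])
    k23 <- pair_key(f[, 2], f[, 3])
    k13 <- pair_key(f[, 1], f[, 3])
    keys <- c(k12, k23, k13)
    uk <- unique(keys)
    idx <- match(keys, uk) + nv
    a <- floor(uk / (nv + 1))
    b <- uk - a * (nv + 1)
    mids <- (v[a, , drop = FALSE] + v[b, , drop = FALSE]) / 2
    nf <- nrow(f)
    m12 <- idx[seq_len(nf)]
    m23 <- idx[nf + seq_len(nf)]
    m13 <- idx[2L * nf + seq_len(nf)]
    v <- rbind(v, mids)
    f <- rbind(
      cbind(f[, 1], m12, m13),
      cbind(f[, 2], m23, m12),
      cbind(f[, 3], m13, m23),
      cbind(m12, m23, m13)
    )
  }
  v <- v * (radius / sqrt(rowSums(v^2)))
  triangle_mesh(v, f, name = sprintf("icosphere_s%d_r%g", subdivisions, radius))
}
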
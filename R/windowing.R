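# Neighbor graph, edge statistics and sliding-window membership.

#' Build the vertex neighbor graph of a mesh
#'
#' Collects each undirected mesh edge once, with Euclidean lengths between
#' endpoint coordinates, plus an adjacency list used by nearest-neighbor
#' smoothing and the FWHM estimator.
#'
#' @param mesh an `lsctp_mesh`.
#' @return object of class `neighbor_graph`: `n_vertices`, `edges` (E x 2,
#'   1-based), `lengths` (mm), `adj` (per-vertex neighbor list), `dv`
#'   (mean edge length).
#' @export
build_neighbor_graph <- function(mesh) {
  f <- mesh$faces
  nv <- n_vertices(mesh)
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(1L, 3L)])
  a <- pmin(e[, 1L], e[, 2L])
  b <- pmax(e[, 1L], e[, 2L])
  key <- as.double(a) * (nv + 1) + as.double(b)
  keep <- !duplicated(key)
  a <- a[keep]; b <- b[keep]
  if (length(a) == 0L) lsctp_abort("mesh has no edges", "lsctp_invariant_error")
  d <- sqrt(rowSums((mesh$vertices[a, , drop = FALSE] -
                       mesh$vertices[b, , drop = FALSE])^2))
  if (any(d <= 0)) {
    lsctp_abort(sprintf("zero-length edge between vertices %d and %d",
                        a[which(d <= 0)[1L]], b[which(d <= 0)[1L]]),
                "lsctp_degenerate_error")
  }
  deg <- tabulate(c(a, b), nbins = nv)
  if (any(deg == 0L)) {
    lsctp_warn(sprintf("%d isolated vertices in mesh '%s'",
                       sum(deg == 0L), mesh$name), "lsctp_isolated_vertex_warning")
  }
  adj <- vector("list", nv)
  ord <- order(c(a, b))
  nb <- c(b, a)[ord]
  adj <- split(nb, factor(c(a, b)[ord], levels = seq_len(nv)))
  names(adj) <- NULL
  structure(
    list(n_vertices = nv, edges = cbind(a, b, deparse.level = 0L),
         lengths = d, adj = adj, dv = mean(d)),
    class = "neighbor_graph"
  )
}

as_neighbor_graph <- function(x) {
  if (inherits(x, "neighbor_graph")) x else build_neighbor_graph(x)
}

#' Vertices inside a sliding window
#'
#' Window membership is the set of vertices within `diameter / 2` of the
#' center under the Euclidean (chordal) distance on the coordinates of the
#' analysis mesh. On a registration sphere, window "mm" are therefore
#' sphere-coordinate mm, not cortical mm.
#'
#' @param mesh an `lsctp_mesh` (the analysis mesh, typically the sphere).
#' @param center 1-based vertex index.
#' @param diameter window diameter in mesh mm.
#' @return list with `center`, `diameter` and `members` (sorted 1-based
#'   indices, always including the center).
#' @export
window_members <- function(mesh, center, diameter) {
  if (diameter <= 0) lsctp_abort("diameter must be > 0", "lsctp_parameter_error")
  nv <- n_vertices(mesh)
  if (center < 1L || center > nv) lsctp_abort("center out of range", "lsctp_bounds_error")
  d2 <- rowSums((mesh$vertices -
                   matrix(mesh$vertices[center, ], nv, 3L, byrow = TRUE))^2)
  members <- which(d2 <= (diameter / 2)^2)
  list(center = as.integer(center), diameter = diameter,
       members = sort(unique(c(as.integer(center), members))))
}

#' All sliding windows of one diameter
#'
#' Vectorized batch form of [window_members()]: member lists for every
#' requested center, chunked so the distance computation stays at
#' O(chunk x V) memory. Precomputing these and passing them to
#' [lsctp_map()] avoids recomputing windows across maps of one diameter.
#'
#' @param mesh the analysis mesh.
#' @param diameter window diameter (mesh mm).
#' @param centers 1-based center indices; default all vertices.
#' @param chunk internal block size.
#' @return list of sorted member index vectors, one per center.
#' @export
vertex_windows <- function(mesh, diameter, centers = NULL, chunk = 256L) {
  if (diameter <= 0) lsctp_abort("diameter must be > 0", "lsctp_parameter_error")
  v <- mesh$vertices
  nv <- nrow(v)
  centers <- centers %||% seq_len(nv)
  r2 <- (diameter / 2)^2
  sq <- rowSums(v^2)
  out <- vector("list", length(centers))
  for (start in seq(1L, length(centers), by = chunk)) {
    span <- start:min(start + chunk - 1L, length(centers))
    cs <- centers[span]
    # squared chordal distance via |a|^2 + |b|^2 - 2 a.b
    g <- v[cs, , drop = FALSE] %*% t(v)
    d2 <- outer(sq[cs], sq, "+") - 2 * g
    for (i in seq_along(cs)) {
      m <- which(d2[i, ] <= r2 + 1e-9 * max(r2, 1))
      out[[span[i]]] <- sort(unique(c(cs[i], m)))
    }
  }
  out
}

#' Edge statistics of a vertex map
#'
#' The three ingredients of the surface FWHM estimator: `dv`, the mean
#' inter-neighbor (edge) distance; `var_ds`, the variance of value
#' differences across edges; `var_s`, the variance of the vertex values.
#' Only edges with both endpoints inside the mask contribute, and `var_s`
#' is taken over masked vertices, so medial-wall zeros cannot inflate the
#' smoothness estimate. Variances use the population (divide-by-n)
#' convention throughout.
#'
#' @param graph a `neighbor_graph` (or a mesh, converted on the fly).
#' @param values numeric per-vertex map.
#' @param mask optional logical vertex mask; default all vertices.
#' @return list of class `edge_stats`: `dv`, `var_ds`, `var_s`, `n_edges`,
#'   `n_vertices`.
#' @export
edge_statistics <- function(graph, values, mask = NULL) {
  g <- as_neighbor_graph(graph)
  if (length(values) != g$n_vertices) {
    lsctp_abort("map length does not match vertex count", "lsctp_dimension_error")
  }
  if (any(!is.finite(values))) lsctp_abort("non-finite map value", "lsctp_invariant_error")
  mask <- mask %||% rep(TRUE, g$n_vertices)
  if (sum(mask) < 2L) lsctp_abort("mask holds fewer than 2 vertices", "lsctp_insufficient_data_error")
  inside <- mask[g$edges[, 1L]] & mask[g$edges[, 2L]]
  if (!any(inside)) lsctp_abort("mask contains no interior edge", "lsctp_insufficient_data_error")
  ds <- values[g$edges[inside, 1L]] - values[g$edges[inside, 2L]]
  structure(
    list(
      dv = mean(g$lengths[inside]),
      var_ds = pop_var(ds),
      var_s = pop_var(values[mask]),
      n_edges = sum(inside),
      n_vertices = sum(mask)
    ),
    class = "edge_stats"
  )
}
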
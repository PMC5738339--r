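# The LSCTP statistic: per-vertex all-pairs inter-subject correlation of
# windowed thickness profiles, averaged on the Fisher z scale.

FISHER_CLAMP <- 1 - 1e-7

#' All pairwise profile correlations within one window
#'
#' Correlates every unordered pair of subjects' thickness profiles over the
#' vertices of one window. With n subjects this yields n(n-1)/2 Pearson
#' correlations, returned in lexicographic pair order ((1,2), (1,3), ...,
#' (2,3), ...).
#'
#' @param window_data subjects x window-vertices numeric matrix.
#' @return numeric vector of length `n (n - 1) / 2`.
#' @export
pairwise_profile_correlations <- function(window_data) {
  x <- as.matrix(window_data)
  n <- nrow(x)
  if (n < 2L) lsctp_abort("need at least 2 subjects", "lsctp_insufficient_data_error")
  if (ncol(x) < 3L) {
    lsctp_abort("need at least 3 window vertices for a meaningful correlation",
                "lsctp_insufficient_data_error")
  }
  dev <- x - rowMeans(x)
  ss <- rowSums(dev^2)
  if (any(ss == 0)) {
    sid <- (rownames(x) %||% as.character(seq_len(n)))[which(ss == 0)[1L]]
    lsctp_abort(sprintf("constant windowed profile for subject '%s': correlation undefined", sid),
                "lsctp_constant_profile_error")
  }
  C <- tcrossprod(dev / sqrt(ss))
  # lower triangle in column-major order enumerates pairs lexicographically
  pmin(pmax(C[lower.tri(C)], -1), 1)
}

#' Average correlations on the Fisher z scale
#'
#' Correlations are clamped to magnitude `1 - 1e-7` (identical profiles
#' would otherwise map to infinite z), transformed with atanh, averaged,
#' and back-transformed with tanh.
#'
#' @param correlations numeric vector with entries in `[-1, 1]`.
#' @return the back-transformed mean, strictly inside `(-1, 1)`.
#' @export
fisher_average <- function(correlations) {
  if (length(correlations) == 0L) {
    lsctp_abort("cannot average an empty set of correlations", "lsctp_insufficient_data_error")
  }
  if (any(abs(correlations) > 1 + 1e-12) || any(!is.finite(correlations))) {
    lsctp_abort("correlations must lie in [-1, 1]", "lsctp_parameter_error")
  }
  r <- pmin(pmax(correlations, -FISHER_CLAMP), FISHER_CLAMP)
  tanh(mean(atanh(r)))
}

#' Compute an LSCTP map
#'
#' For every vertex, thickness values of all subjects over the window
#' members are extracted and all subject pairs are correlated; the
#' correlations are Fisher-z averaged into one per-vertex similarity.
#' A vertex is excluded when (i) any subject has zero thickness anywhere in
#' its window (the medial-wall rule), (ii) the window holds fewer than 3
#' vertices, or (iii) some subject's windowed profile is constant (counted
#' separately). Exclusion reasons are tallied in `exclusions`.
#'
#' @param cohort a [cohort_thickness()] matrix.
#' @param mesh the analysis mesh (windows use chordal distance on its
#'   coordinates).
#' @param diameter window diameter in mesh mm.
#' @param windows optional precomputed window list from `vertex_windows`
#'   (reused across calls for speed).
#' @return object of class `lsctp_map`: `mean_r` (NA where excluded),
#'   `included` (logical mask), `diameter`, `n_subjects`, `n_pairs`,
#'   `mesh_name`, `exclusions`.
#' @export
lsctp_map <- function(cohort, mesh, diameter, windows = NULL) {
  if (diameter <= 0) lsctp_abort("diameter must be > 0", "lsctp_parameter_error")
  nv <- n_vertices(mesh)
  if (ncol(cohort) != nv) {
    lsctp_abort(sprintf("cohort has %d vertices but mesh '%s' has %d",
                        ncol(cohort), mesh$name, nv), "lsctp_dimension_error")
  }
  n <- nrow(cohort)
  windows <- windows %||% vertex_windows(mesh, diameter)
  cohort_un <- unclass(cohort)
  has_zero <- colSums(cohort_un == 0) > 0L  # per vertex: any subject at 0
  mean_r <- rep(NA_real_, nv)
  included <- rep(FALSE, nv)
  n_small <- 0L; n_zero <- 0L; n_const <- 0L
  cohort_m <- cohort_un
  for (v in seq_len(nv)) {
    w <- windows[[v]]
    if (length(w) < 3L) { n_small <- n_small + 1L; next }
    if (any(has_zero[w])) { n_zero <- n_zero + 1L; next }
    x <- cohort_m[, w, drop = FALSE]
    dev <- x - rowMeans(x)
    ss <- rowSums(dev^2)
    if (any(ss == 0)) { n_const <- n_const + 1L; next }
    C <- tcrossprod(dev / sqrt(ss))
    r <- pmin(pmax(C[lower.tri(C)], -FISHER_CLAMP), FISHER_CLAMP)
    mean_r[v] <- tanh(mean(atanh(r)))
    included[v] <- TRUE
  }
  if (!any(included)) {
    lsctp_warn("all vertices excluded: empty LSCTP map", "lsctp_empty_map_warning")
  }
  structure(
    list(mean_r = mean_r, included = included, diameter = diameter,
         n_subjects = n, n_pairs = n * (n - 1L) / 2L,
         mesh_name = mesh$name,
         exclusions = c(window_too_small = n_small, zero_thickness = n_zero,
                        constant_profile = n_const)),
    class = "lsctp_map"
  )
}

#' @export
print.lsctp_map <- function(x, ...) {
  cat(sprintf(
    "<lsctp_map: diameter %g mm, %d subjects (%d pairs), %d/%d vertices included>\n",
    x$diameter, x$n_subjects, x$n_pairs, sum(x$included), length(x$included)
  ))
  invisible(x)
}

#' Harmonize inclusion masks across window sizes
#'
#' Larger windows exclude more vertices under the zero-thickness rule. To
#' make maps of different diameters comparable, every map's inclusion mask
#' is intersected with the mask of the largest-diameter map in the list.
#'
#' @param maps list of `lsctp_map`s sharing mesh and cohort.
#' @return the list with harmonized `included` masks (and `mean_r` set to
#'   NA outside them).
#' @export
harmonize_masks <- function(maps) {
  if (length(maps) == 0L) lsctp_abort("empty map list", "lsctp_parameter_error")
  nv <- length(maps[[1L]]$included)
  if (any(vapply(maps, function(m) length(m$included), integer(1)) != nv)) {
    lsctp_abort("maps computed on different meshes", "lsctp_dimension_error")
  }
  ref <- maps[[which.max(vapply(maps, `[[`, numeric(1), "diameter"))]]$included
  out <- lapply(maps, function(m) {
    m$included <- m$included & ref
    m$mean_r[!m$included] <- NA_real_
    m
  })
  if (!any(out[[1L]]$included)) {
    lsctp_warn("harmonized masks are empty", "lsctp_empty_map_warning")
  }
  out
}

#' Export an LSCTP map
#'
#' Writes the per-vertex similarity as a FreeSurfer morph file (excluded
#' vertices as 0) plus a companion label file recording the inclusion
#' mask, or as a TSV table.
#'
#' @param map an `lsctp_map`.
#' @param path output path; `format = "morph"` writes `path` and
#'   `<path>.label`.
#' @param format `"morph"` or `"tsv"`.
#' @param mesh optional mesh for label coordinates.
#' @export
write_lsctp_map <- function(map, path, format = c("morph", "tsv"), mesh = NULL) {
  format <- match.arg(format)
  if (format == "morph") {
    vals <- ifelse(map$included, map$mean_r, 0)
    write_morph(vals, path)
    write_label(map$included, paste0(path, ".label"), mesh = mesh)
  } else {
    df <- data.frame(
      vertex = seq_along(map$mean_r) - 1L,
      mean_r = ifelse(map$included, map$mean_r, NA_real_),
      included = as.integer(map$included)
    )
    con <- file(path, "w")
    writeLines(sprintf("# LSCTP map: diameter_mm=%g n_subjects=%d n_pairs=%d (0-based vertices)",
                       map$diameter, map$n_subjects, map$n_pairs), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  invisible(path)
}
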
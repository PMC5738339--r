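# Monte Carlo null distributions for LSCTP maps: per-subject spatial
# shuffling within the cortex mask, optional smoothing of the shuffled
# data back to each subject's observed smoothness, null map computation
# and empirical critical thresholds.

#' Shuffle a vertex map within a mask
#'
#' Values at masked vertices are replaced by a uniform random permutation
#' of themselves (the multiset is preserved); values outside the mask are
#' untouched. Deterministic given the seed; the caller's RNG state is
#' left unchanged.
#'
#' @param values numeric per-vertex map.
#' @param mask logical vertex mask (nonempty).
#' @param seed integer seed.
#' @return the shuffled map.
#' @export
shuffle_within_mask <- function(values, mask, seed) {
  if (!any(mask)) lsctp_abort("empty mask", "lsctp_parameter_error")
  idx <- which(mask)
  out <- values
  # sample.int, not sample(idx): a length-1 idx must permute to itself
  out[idx] <- with_seed(seed, values[idx[sample.int(length(idx))]])
  out
}

#' Monte Carlo null distributions for LSCTP
#'
#' Implements the shuffling pipeline: per replicate, each subject's
#' thickness map is independently spatially shuffled within the gray-matter
#' mask (destroying spatial structure while preserving the value
#' distribution); optionally each shuffled map is then smoothed by
#' nearest-neighbor averaging until its estimated FWHM matches that
#' subject's observed (true-data) FWHM, since unsmoothed shuffles are far
#' rougher than real cortical data and would understate chance similarity.
#' Null LSCTP maps are computed at every requested diameter and the
#' per-vertex values of included vertices are pooled globally across
#' replicates into one empirical distribution per diameter.
#'
#' @param cohort a [cohort_thickness()] matrix (zeros outside the cortex).
#' @param mesh analysis mesh.
#' @param mask logical gray-matter mask (shuffling domain). Defaults to
#'   vertices where no subject has zero thickness.
#' @param diameters window diameters (mm).
#' @param n_replicates number of shuffle replicates pooled.
#' @param match_smoothness smooth shuffled maps to each subject's observed
#'   FWHM (in dv units, so the choice of reference mesh cancels).
#' @param base_seed integer; per-(replicate, subject) seeds are derived
#'   from it with a splittable counter scheme.
#' @param max_iterations smoothing search bound per subject.
#' @return named list (one element per diameter) of `lsctp_null` objects:
#'   `diameter`, `values` (pooled null LSCTP values), `n_replicates`,
#'   `seeds`, `smoothed`, `iterations` (replicate x subject matrix of
#'   smoothing counts).
#' @export
simulate_null <- function(cohort, mesh, mask = NULL, diameters = 8,
                          n_replicates = 20L, match_smoothness = TRUE,
                          base_seed = 1L, max_iterations = 200L) {
  if (any(diameters <= 0)) lsctp_abort("diameters must be > 0", "lsctp_parameter_error")
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 1L) lsctp_abort("n_replicates must be >= 1", "lsctp_parameter_error")
  nv <- n_vertices(mesh)
  if (ncol(cohort) != nv) lsctp_abort("cohort/mesh vertex mismatch", "lsctp_dimension_error")
  graph <- build_neighbor_graph(mesh)
  mask <- mask %||% (colSums(unclass(cohort) == 0) == 0L)
  if (!any(mask)) lsctp_abort("empty gray-matter mask", "lsctp_parameter_error")
  n_sub <- nrow(cohort)
  # observed per-subject smoothness, in dv units so any reference mesh
  # yields the same iteration counts
  true_fwhm <- if (match_smoothness) {
    vapply(seq_len(n_sub), function(s) {
      es <- edge_statistics(graph, cohort[s, ], mask)
      estimate_fwhm(es) / es$dv
    }, numeric(1))
  } else rep(NA_real_, n_sub)
  windows_by_d <- lapply(diameters, function(d) vertex_windows(mesh, d))
  pooled <- lapply(diameters, function(d) list())
  iter_mat <- matrix(0L, n_replicates, n_sub)
  seeds <- integer(n_replicates)
  for (rep_i in seq_len(n_replicates)) {
    seeds[rep_i] <- derive_seed(base_seed, rep_i, 0L)
    shuffled <- unclass(cohort)
    for (s in seq_len(n_sub)) {
      sh <- shuffle_within_mask(cohort[s, ], mask, derive_seed(base_seed, rep_i, s))
      if (match_smoothness) {
        fit <- tryCatch(
          smooth_to_target(graph, sh, true_fwhm[s], max_iterations = max_iterations,
                           mask = mask, dv_units = TRUE),
          lsctp_unbracketed_target_error = function(e) {
            lsctp_abort(sprintf(
              "replicate %d aborted: smoothness matching failed for subject %d (%s)",
              rep_i, s, conditionMessage(e)
            ), "lsctp_smoothness_match_error")
          }
        )
        sh <- fit$values
        iter_mat[rep_i, s] <- fit$iterations
      }
      shuffled[s, ] <- sh
    }
    null_cohort <- cohort_thickness(shuffled, subject_ids = rownames(cohort))
    for (k in seq_along(diameters)) {
      m <- suppressWarnings(
        lsctp_map(null_cohort, mesh, diameters[k], windows = windows_by_d[[k]])
      )
      pooled[[k]][[rep_i]] <- m$mean_r[m$included]
    }
  }
  out <- lapply(seq_along(diameters), function(k) {
    structure(
      list(diameter = diameters[k], values = unlist(pooled[[k]]),
           n_replicates = n_replicates, seeds = seeds,
           smoothed = match_smoothness, iterations = iter_mat,
           base_seed = base_seed),
      class = "lsctp_null"
    )
  })
  names(out) <- sprintf("d%g", diameters)
  out
}

#' Empirical critical LSCTP threshold
#'
#' Upper-tail critical value from a pooled null distribution, with the
#' plus-one correction: the empirical tail probability of a candidate t is
#' `(#\{null >= t\} + 1) / (n + 1)`, which can never reach zero at finite
#' replicates. The threshold returned is the k-th largest null value with
#' `k = floor(p * (n + 1))`. When `p < 1 / (n + 1)` the requested tail is
#' beyond empirical resolution: the maximum null value is returned with a
#' warning and attribute `beyond_resolution = TRUE`.
#'
#' @param null an `lsctp_null` object (or a bare numeric vector of null
#'   values).
#' @param p upper-tail probability, strictly between 0 and 1.
#' @return the critical threshold (numeric scalar).
#' @export
critical_value <- function(null, p) {
  vals <- if (inherits(null, "lsctp_null")) null$values else as.numeric(null)
  if (length(vals) == 0L) lsctp_abort("empty null distribution", "lsctp_insufficient_data_error")
  if (p <= 0 || p >= 1) lsctp_abort("p must be in (0, 1)", "lsctp_parameter_error")
  n <- length(vals)
  k <- floor(p * (n + 1))
  if (k < 1) {
    lsctp_warn(sprintf(
      "p = %g is beyond the resolution of %d null values (limit 1/%d); returning the maximum",
      p, n, n + 1L
    ), "lsctp_resolution_warning")
    return(structure(max(vals), beyond_resolution = TRUE))
  }
  sort(vals, decreasing = TRUE)[k]
}

#' Threshold an LSCTP map
#'
#' Removes vertices with `mean_r` below the threshold from the inclusion
#' mask; values themselves are untouched.
#'
#' @param map an `lsctp_map`.
#' @param threshold critical similarity value.
#' @return the thresholded `lsctp_map`.
#' @export
threshold_map <- function(map, threshold) {
  if (!is.finite(threshold)) lsctp_abort("threshold must be finite", "lsctp_parameter_error")
  drop <- map$included & (map$mean_r < threshold)
  map$included[drop] <- FALSE
  map
}

#' Tabulate critical thresholds
#'
#' @param nulls list of `lsctp_null` objects (one per diameter).
#' @param p_levels upper-tail probabilities (columns).
#' @return data.frame: one row per window diameter, one column per p level,
#'   plus `smoothed` and `n_null`.
#' @export
threshold_table <- function(nulls, p_levels = c(0.05, 0.001, 1e-6)) {
  rows <- lapply(nulls, function(nd) {
    th <- vapply(p_levels, function(p) {
      suppressWarnings(as.numeric(critical_value(nd, p)))
    }, numeric(1))
    c(diameter_mm = nd$diameter, stats::setNames(th, sprintf("p%g", p_levels)),
      smoothed = as.integer(nd$smoothed), n_null = length(nd$values))
  })
  as.data.frame(do.call(rbind, rows), row.names = FALSE)
}

#' Persist a null distribution
#'
#' Writes the pooled null values as one plain-text value per line, with a
#' JSON sidecar recording diameter, replicate count, seeds and smoothing
#' iteration counts.
#'
#' @param null an `lsctp_null`.
#' @param path output path for the values; the sidecar goes to
#'   `<path>.json`.
#' @export
write_null_distribution <- function(null, path) {
  writeLines(format(null$values, digits = 17, scientific = TRUE, trim = TRUE), path)
  side <- list(
    diameter_mm = null$diameter,
    n_replicates = null$n_replicates,
    base_seed = null$base_seed,
    seeds = null$seeds,
    smoothed = null$smoothed,
    iterations_per_subject = null$iterations
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
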
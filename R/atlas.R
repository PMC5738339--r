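# ROI / atlas summaries of LSCTP maps: per-region means, Monte Carlo
# baselines per region, and rank stability across window sizes.

#' Bundle named vertex masks into a parcellation
#'
#' @param masks named list of logical vertex masks of equal length (e.g.
#'   seven functional networks, or histological areas).
#' @return the validated list, class `parcellation_masks`.
#' @export
parcellation_masks <- function(masks) {
  if (length(masks) == 0L) lsctp_abort("empty parcellation", "lsctp_parameter_error")
  nms <- names(masks)
  if (is.null(nms) || any(!nzchar(nms)) || anyDuplicated(nms)) {
    lsctp_abort("masks must carry unique nonempty names", "lsctp_parameter_error")
  }
  lens <- lengths(masks)
  if (length(unique(lens)) != 1L) {
    lsctp_abort("masks differ in length", "lsctp_dimension_error")
  }
  structure(lapply(masks, as.logical), class = "parcellation_masks")
}

#' Read a parcellation from a TSV of (vertex, roi_name)
#'
#' Expects two tab-separated columns, 0-based vertex index and region name;
#' `#` comment lines are ignored.
#'
#' @param path file path.
#' @param n_vertices mesh vertex count.
#' @return a [parcellation_masks()] object.
#' @export
read_parcellation_tsv <- function(path, n_vertices) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE, col.names = c("vertex", "roi"))
  if (any(df$vertex < 0) || any(df$vertex >= n_vertices)) {
    lsctp_abort("parcellation vertex index out of range", "lsctp_bounds_error")
  }
  masks <- lapply(split(df$vertex, df$roi), function(idx) {
    m <- rep(FALSE, n_vertices)
    m[idx + 1L] <- TRUE
    m
  })
  parcellation_masks(masks)
}

#' Mean LSCTP per region
#'
#' Averages `mean_r` (on the r scale) over the intersection of each region
#' with the map's inclusion mask. Vertices excluded from the map are
#' dropped from the denominator, never zero-filled; an empty intersection
#' yields NA.
#'
#' @param map an `lsctp_map`.
#' @param rois a [parcellation_masks()] object (or a named list of masks).
#' @param scale `"r"` (default, matches how maps are displayed) or `"z"`
#'   (Fisher scale, for statistical follow-up).
#' @return data.frame with columns `roi`, `mean`, `n_vertices`.
#' @export
roi_mean_lsctp <- function(map, rois, scale = c("r", "z")) {
  scale <- match.arg(scale)
  if (!inherits(rois, "parcellation_masks")) rois <- parcellation_masks(rois)
  if (length(rois[[1L]]) != length(map$included)) {
    lsctp_abort("parcellation does not match map vertex count", "lsctp_dimension_error")
  }
  vals <- map$mean_r
  if (scale == "z") vals <- atanh(pmin(pmax(vals, -FISHER_CLAMP), FISHER_CLAMP))
  rows <- lapply(names(rois), function(nm) {
    sel <- rois[[nm]] & map$included
    data.frame(
      roi = nm,
      mean = if (any(sel)) mean(vals[sel]) else NA_real_,
      n_vertices = sum(sel),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Region baselines from Monte Carlo maps
#'
#' Per region: each replicate's null map is averaged over the region, then
#' the per-replicate means are averaged again into one grand mean — the
#' chance similarity level for that region and window size.
#'
#' @param null_maps list of `lsctp_map`s, one per Monte Carlo replicate.
#' @param rois a [parcellation_masks()] object.
#' @return data.frame: `roi`, `grand_mean`, `n_replicates`, `sd_across_replicates`.
#' @export
null_roi_means <- function(null_maps, rois) {
  if (length(null_maps) == 0L) lsctp_abort("need at least one replicate map", "lsctp_parameter_error")
  if (!inherits(rois, "parcellation_masks")) rois <- parcellation_masks(rois)
  per_rep <- lapply(null_maps, function(m) roi_mean_lsctp(m, rois)$mean)
  M <- do.call(rbind, per_rep)  # replicates x rois
  data.frame(
    roi = names(rois),
    grand_mean = colMeans(M, na.rm = TRUE),
    n_replicates = length(null_maps),
    sd_across_replicates = apply(M, 2L, stats::sd, na.rm = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Rank regions by mean LSCTP across window sizes
#'
#' Ranks the regions of each diameter's table (rank 1 = highest mean; ties
#' share the average rank) and counts how many regions change rank across
#' diameters — the rank-stability summary.
#'
#' @param tables named list (one per diameter) of data.frames from
#'   [roi_mean_lsctp()], all over the same region set.
#' @return list: `ranks` (matrix, regions x diameters), `n_unstable`
#'   (regions whose rank varies), `unstable_rois` (their names).
#' @export
rank_by_window <- function(tables) {
  if (length(tables) == 0L) lsctp_abort("empty table list", "lsctp_parameter_error")
  rois <- tables[[1L]]$roi
  for (t in tables) {
    if (!identical(sort(t$roi), sort(rois))) {
      lsctp_abort("tables cover different region sets", "lsctp_parameter_error")
    }
  }
  ranks <- vapply(tables, function(t) {
    m <- t$mean[match(rois, t$roi)]
    rank(-m, ties.method = "average", na.last = "keep")
  }, numeric(length(rois)))
  ranks <- matrix(ranks, nrow = length(rois),
                  dimnames = list(rois, names(tables)))
  unstable <- apply(ranks, 1L, function(r) length(unique(r[!is.na(r)])) > 1L)
  list(ranks = ranks, n_unstable = sum(unstable),
       unstable_rois = rois[unstable])
}

#' Long-format region summary across diameters
#'
#' @param maps named list of `lsctp_map`s (e.g. a sweep).
#' @param rois a [parcellation_masks()] object.
#' @return data.frame with columns `diameter_mm`, `roi`, `mean`,
#'   `n_vertices` — one row per diameter and region.
#' @export
roi_summary_long <- function(maps, rois) {
  rows <- lapply(maps, function(m) {
    t <- roi_mean_lsctp(m, rois)
    data.frame(diameter_mm = m$diameter, t, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
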
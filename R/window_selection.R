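# Window-size selection: sweep LSCTP maps over diameters, then map the
# local variability (SD) of the similarity map inside a second sliding
# window and average it per primary diameter. High local SD indicates a
# map that still differentiates neighboring anatomy; very small primary
# windows are noise-dominated and very large ones wash structure out, so
# the mean local SD peaks near the spatial scale of real differentiation.

#' Sweep LSCTP maps over window diameters
#'
#' Computes one LSCTP map per diameter and harmonizes all inclusion masks
#' to the largest diameter's mask so the maps stay comparable.
#'
#' @param cohort a [cohort_thickness()] matrix.
#' @param mesh analysis mesh.
#' @param diameters strictly ascending window diameters (mm).
#' @return list of `lsctp_map`s, one per diameter, masks harmonized.
#' @export
lsctp_sweep <- function(cohort, mesh, diameters) {
  if (length(diameters) == 0L || any(diameters <= 0) || is.unsorted(diameters, strictly = TRUE)) {
    lsctp_abort("diameters must be strictly ascending and > 0", "lsctp_parameter_error")
  }
  maps <- lapply(diameters, function(d) lsctp_map(cohort, mesh, d))
  if (length(maps) > 1L) maps <- harmonize_masks(maps)
  names(maps) <- sprintf("d%g", diameters)
  maps
}

#' Local standard deviation of an LSCTP map
#'
#' Per vertex, the sample SD of `mean_r` over the included vertices of a
#' second sliding window. Vertices whose window holds fewer than 2
#' included members are undefined (NA).
#'
#' @param map an `lsctp_map`.
#' @param mesh analysis mesh.
#' @param sd_diameter diameter (mm) of the variability window.
#' @param windows optional precomputed window list.
#' @return numeric per-vertex map (NA where undefined).
#' @export
local_sd_map <- function(map, mesh, sd_diameter, windows = NULL) {
  if (sd_diameter <= 0) lsctp_abort("sd_diameter must be > 0", "lsctp_parameter_error")
  if (!any(map$included)) lsctp_abort("map has no included vertex", "lsctp_insufficient_data_error")
  windows <- windows %||% vertex_windows(mesh, sd_diameter)
  vapply(seq_along(windows), function(v) {
    w <- windows[[v]]
    vals <- map$mean_r[w[map$included[w]]]
    if (length(vals) < 2L) NA_real_ else stats::sd(vals)
  }, numeric(1))
}

#' Mean local SD per primary window diameter
#'
#' Averages the defined values of [local_sd_map()] for every combination
#' of primary diameter (the maps of a sweep) and variability-window
#' diameter. Undefined cells are dropped from the mean, never zero-filled
#' (zero-filling would bias selection toward large windows). Also reports,
#' per variability diameter, the primary diameter with the highest mean
#' local SD.
#'
#' @param sweep list of `lsctp_map`s from [lsctp_sweep()].
#' @param mesh analysis mesh.
#' @param sd_diameters variability-window diameters (mm).
#' @return list: `table` (data.frame, rows = primary diameter, one column
#'   per sd diameter; NA where no cell was defined) and `argmax`
#'   (named numeric: best primary diameter per sd diameter).
#' @export
mean_sd_table <- function(sweep, mesh, sd_diameters = c(8, 16, 32)) {
  if (length(sweep) == 0L) lsctp_abort("empty sweep", "lsctp_parameter_error")
  prim <- vapply(sweep, `[[`, numeric(1), "diameter")
  cols <- lapply(sd_diameters, function(sd_d) {
    win <- vertex_windows(mesh, sd_d)
    vapply(sweep, function(m) {
      s <- local_sd_map(m, mesh, sd_d, windows = win)
      if (all(is.na(s))) NA_real_ else mean(s, na.rm = TRUE)
    }, numeric(1))
  })
  tab <- data.frame(primary_diameter_mm = prim, cols)
  colnames(tab) <- c("primary_diameter_mm", sprintf("sd%g", sd_diameters))
  argmax <- vapply(seq_along(sd_diameters), function(j) {
    col <- cols[[j]]
    if (all(is.na(col))) NA_real_ else prim[which.max(col)]
  }, numeric(1))
  names(argmax) <- sprintf("sd%g", sd_diameters)
  list(table = tab, argmax = argmax)
}

#' Write a mean-SD selection table as TSV
#'
#' @param selection result of [mean_sd_table()].
#' @param path output path.
#' @export
write_selection_table <- function(selection, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# mean local SD of LSCTP per primary window diameter (mm); columns = variability window diameter (mm)", con)
  utils::write.table(selection$table, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
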
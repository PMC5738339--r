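# Synthetic spherical cohorts with controllable shared-profile structure.
#
# Each subject's thickness is a base level plus a spatially smooth field.
# Inside a region of shared strength rho the field mixes one common
# component c(v) (the same for every subject) with a per-subject
# idiosyncratic component e_s(v):
#
#   thickness_s(v) = base + sd * ( sqrt(rho) c(v) + sqrt(1 - rho) e_s(v) )
#
# Both components are unit-variance smoothed white noise, so rho equals
# the expected inter-subject Pearson correlation of the profiles — the
# quantity the sliding-window statistic estimates. Outside all regions
# rho = 0 (purely idiosyncratic cortex); medial-wall vertices are set to
# exactly 0, the missingness code.

# Unit-variance smooth field: white noise, nearest-neighbor smoothed,
# centered and rescaled over the non-medial vertices.
smooth_unit_field <- function(graph, smooth_iterations, medial) {
  x <- stats::rnorm(graph$n_vertices)
  x <- nn_smooth(graph, x, smooth_iterations)
  keep <- !medial
  x <- x - mean(x[keep])
  s <- sqrt(pop_var(x[keep]))
  if (s == 0) lsctp_abort("degenerate smooth field", "lsctp_degenerate_error")
  x / s
}

#' Simulate a cohort of thickness maps on a mesh
#'
#' @param mesh analysis mesh (typically [make_icosphere()]).
#' @param n_subjects number of subjects (>= 2).
#' @param regions list of `list(mask = <logical>, rho = <0..1>)` entries;
#'   masks may not overlap. `rho` is the generative inter-subject profile
#'   correlation inside the region.
#' @param base_thickness mean thickness (mm); 2.5 mm is a typical human
#'   cortical mean.
#' @param noise_sd standard deviation (mm) of the spatial profile around
#'   the base; 0.5 mm is a realistic between-subject scale.
#' @param smooth_iterations nearest-neighbor smoothing iterations applied
#'   to the generating fields; sets the spatial scale of the profiles
#'   (FWHM grows roughly as 1.6 sqrt(iterations) in units of the mean edge
#'   length). The default of 2 keeps the profile scale well below the
#'   default 8 mm analysis window, the regime in which the generative
#'   `rho` is realized as the expected windowed Pearson correlation;
#'   larger values (e.g. 12, matching the smoothness of real unsmoothed
#'   thickness data) emulate the low-degrees-of-freedom regime where
#'   windowed correlations attenuate.
#' @param medial_mask logical mask of medial-wall vertices set to exactly
#'   0 (default none).
#' @param seed integer seed; the cohort is deterministic given it.
#' @return list: `cohort` (a [cohort_thickness()] matrix), `truth`
#'   (per-vertex generative rho, plus the parameters), `mesh_name`.
#' @export
simulate_cohort <- function(mesh, n_subjects = 42L, regions = list(),
                            base_thickness = 2.5, noise_sd = 0.5,
                            smooth_iterations = 2L, medial_mask = NULL,
                            seed = 1L) {
  nv <- n_vertices(mesh)
  if (n_subjects < 2L) lsctp_abort("need at least 2 subjects", "lsctp_parameter_error")
  if (noise_sd <= 0) lsctp_abort("noise_sd must be > 0", "lsctp_parameter_error")
  medial <- medial_mask %||% rep(FALSE, nv)
  rho_v <- rep(0, nv)
  claimed <- rep(FALSE, nv)
  for (rg in regions) {
    if (any(rg$rho < 0) || any(rg$rho > 1)) {
      lsctp_abort("region rho must be in [0, 1]", "lsctp_parameter_error")
    }
    if (any(claimed & rg$mask)) {
      lsctp_abort("regions may not overlap", "lsctp_parameter_error")
    }
    claimed <- claimed | rg$mask
    rho_v[rg$mask] <- rg$rho
  }
  graph <- build_neighbor_graph(mesh)
  mat <- with_seed(seed, {
    common <- smooth_unit_field(graph, smooth_iterations, medial)
    shared_w <- sqrt(rho_v)
    idio_w <- sqrt(1 - rho_v)
    t(vapply(seq_len(n_subjects), function(s) {
      e <- smooth_unit_field(graph, smooth_iterations, medial)
      th <- base_thickness + noise_sd * (shared_w * common + idio_w * e)
      th <- pmax(th, 0.1)  # keep 0 unambiguous as the missingness code
      th[medial] <- 0
      th
    }, numeric(nv)))
  })
  list(
    cohort = cohort_thickness(mat, sprintf("sim%02d", seq_len(n_subjects))),
    truth = list(
      rho = rho_v, medial = medial, seed = seed,
      base_thickness = base_thickness, noise_sd = noise_sd,
      smooth_iterations = smooth_iterations
    ),
    mesh_name = mesh$name
  )
}

#' Spherical cap mask
#'
#' Convenience region builder: all vertices within a chordal radius of a
#' center vertex.
#'
#' @param mesh the mesh.
#' @param center 1-based vertex index.
#' @param radius cap radius (chordal mm).
#' @return logical vertex mask.
#' @export
cap_mask <- function(mesh, center, radius) {
  w <- window_members(mesh, center, 2 * radius)
  m <- rep(FALSE, n_vertices(mesh))
  m[w$members] <- TRUE
  m
}

#' Write a synthetic cohort to disk
#'
#' Mesh as a FreeSurfer binary surface, one curv file per subject, ground
#' truth as JSON.
#'
#' @param sim result of [simulate_cohort()].
#' @param mesh the mesh it was simulated on.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
write_cohort <- function(sim, mesh, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, "mesh.surf")
  write_surface(mesh, paths)
  for (s in seq_len(nrow(sim$cohort))) {
    p <- file.path(dir, sprintf("%s.curv", rownames(sim$cohort)[s]))
    write_morph(sim$cohort[s, ], p)
    paths <- c(paths, p)
  }
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(sim$truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, truth_path))
}
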
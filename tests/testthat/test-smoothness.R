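test_that("FWHM estimator reproduces its closed forms and limits", {
  # var_ds = var_s: the log argument is 1/2, so FWHM = sqrt(2) * dv
  es <- structure(list(dv = 1, var_ds = 0.3, var_s = 0.3), class = "edge_stats")
  expect_equal(estimate_fwhm(es), sqrt(2), tolerance = 1e-12)
  es$dv <- 2.5
  expect_equal(estimate_fwhm(es), 2.5 * sqrt(2), tolerance = 1e-12)

  # white-noise limit: var_ds = 2 var_s gives zero smoothness
  expect_equal(estimate_fwhm(structure(list(dv = 1, var_ds = 0.6, var_s = 0.3),
                                       class = "edge_stats")), 0)
  # rougher than white noise still reports 0
  expect_equal(estimate_fwhm(structure(list(dv = 1, var_ds = 1, var_s = 0.3),
                                       class = "edge_stats")), 0)
  # constant field: unbounded smoothness sentinel
  expect_identical(estimate_fwhm(structure(list(dv = 1, var_ds = 0, var_s = 0.3),
                                           class = "edge_stats")), Inf)
  expect_error(estimate_fwhm(structure(list(dv = 1, var_ds = 0, var_s = 0),
                                       class = "edge_stats")),
               class = "lsctp_undefined_smoothness_error")
})

test_that("i.i.d. noise has near-zero estimated FWHM across seeds", {
  g <- build_neighbor_graph(sphere3)
  f <- vapply(1:20, function(s) {
    x <- with_seed_test(s, stats::rnorm(642))
    estimate_fwhm(edge_statistics(g, x)) / g$dv
  }, numeric(1))
  # unsmoothed noise: estimates hug the white-noise limit
  expect_lt(mean(f), 0.5)
  expect_lt(mean(f) - 3 * stats::sd(f) / sqrt(20), 0.25)
})

test_that("nearest-neighbor smoothing matches the dense averaging-matrix oracle", {
  g <- build_neighbor_graph(ico)
  expect_equal(nn_smooth(g, rep(2.2, 12), 5), rep(2.2, 12), tolerance = 1e-12)
  x <- with_seed_test(4, stats::rnorm(12))
  expect_identical(nn_smooth(g, x, 0), x)

  # unit impulse: one iteration spreads to 1/6 at the center (self + 5
  # neighbors on the icosahedron), 0 elsewhere in the 2-ring complement
  imp <- c(1, rep(0, 11))
  one <- nn_smooth(g, imp, 1)
  expect_equal(one[1], 1 / 6, tolerance = 1e-12)
  A <- oracle_smooth_matrix(ico)
  expect_equal(one, as.vector(A %*% imp), tolerance = 1e-12)
  expect_equal(nn_smooth(g, imp, 3), as.vector(A %*% A %*% A %*% imp),
               tolerance = 1e-12)

  # vertex-transitive mesh: smoothing preserves the mean exactly
  expect_equal(mean(nn_smooth(g, x, 4)), mean(x), tolerance = 1e-12)

  # masked smoothing never touches out-of-mask values
  g3 <- build_neighbor_graph(sphere3)
  mask <- cap_mask(sphere3, 50, 3)
  y <- with_seed_test(5, stats::rnorm(642))
  sm <- nn_smooth(g3, y, 2, mask = mask)
  expect_identical(sm[!mask], y[!mask])
  expect_false(identical(sm[mask], y[mask]))
})

test_that("smoothing a masked singleton leaves it unchanged", {
  g <- build_neighbor_graph(ico)
  mask <- c(TRUE, rep(FALSE, 11))  # no in-mask neighbor
  x <- 1:12 / 3
  expect_equal(nn_smooth(g, x, 3, mask = mask), x, tolerance = 1e-12)
})

test_that("estimated FWHM grows monotonically with smoothing iterations on noise", {
  g <- build_neighbor_graph(sphere3)
  rho <- vapply(1:20, function(s) {
    x <- with_seed_test(100 + s, stats::rnorm(642))
    f <- vapply(c(1, 2, 4, 8, 16), function(n) {
      estimate_fwhm(edge_statistics(g, nn_smooth(g, x, n)))
    }, numeric(1))
    stats::cor(f, c(1, 2, 4, 8, 16), method = "spearman")
  }, numeric(1))
  expect_gte(mean(rho), 0.95)
})

test_that("FWHM after N iterations is about 1.25 sqrt(N) mm on a 0.8 mm spaced mesh", {
  # calibration constant presumes a mesh whose mean inter-neighbor
  # distance is 0.8 mm; scale the sphere accordingly
  m <- make_icosphere(5, 30.4 * 0.8 / 1.1429)
  g <- build_neighbor_graph(m)
  expect_equal(g$dv, 0.8, tolerance = 0.01)
  for (N in c(9, 16, 25)) {
    ratio <- vapply(1:3, function(s) {
      x <- with_seed_test(200 + s, stats::rnorm(g$n_vertices))
      estimate_fwhm(edge_statistics(g, nn_smooth(g, x, N))) / sqrt(N)
    }, numeric(1))
    expect_equal(mean(ratio), 1.25, tolerance = 0.15,
                 label = sprintf("FWHM/sqrt(N) at N=%d", N))
  }
})

test_that("smooth_to_target picks the iteration count closest to the target", {
  g <- build_neighbor_graph(sphere3)
  x <- with_seed_test(7, stats::rnorm(642))
  # target 0 on rough noise: stay at N = 0
  expect_identical(smooth_to_target(g, x, 0, 50)$iterations, 0L)
  # target equal to the map's own smoothness: N = 0
  own <- estimate_fwhm(edge_statistics(g, x))
  expect_identical(smooth_to_target(g, x, own, 50)$iterations, 0L)

  # white noise toward 1.25 * sqrt(16) mm on a dv = 0.8 mm mesh: N ~ 16
  m <- make_icosphere(5, 30.4 * 0.8 / 1.1429)
  g5 <- build_neighbor_graph(m)
  ns <- vapply(1:4, function(s) {
    x5 <- with_seed_test(300 + s, stats::rnorm(g5$n_vertices))
    smooth_to_target(g5, x5, 1.25 * 4, 100)$iterations
  }, integer(1))
  expect_true(all(abs(ns - 16L) <= 2L))

  err <- expect_error(smooth_to_target(g, x, 1e3, 3),
                      class = "lsctp_unbracketed_target_error")
  expect_match(conditionMessage(err), "best achieved")
})

test_that("matching a smoothness target gives the same N on different reference meshes", {
  # same field, same graph topology, globally rescaled coordinates: dv
  # differs, the dv-unit target does not, so N agrees (within rounding)
  m_a <- make_icosphere(3, 7.6)
  m_b <- make_icosphere(3, 10.3)  # different dv, identical topology
  g_a <- build_neighbor_graph(m_a)
  g_b <- build_neighbor_graph(m_b)
  x <- with_seed_test(9, stats::rnorm(642))
  ref <- nn_smooth(g_a, with_seed_test(10, stats::rnorm(642)), 9)
  t_a <- estimate_fwhm(edge_statistics(g_a, ref)) / g_a$dv
  t_b <- estimate_fwhm(edge_statistics(g_b, ref)) / g_b$dv
  n_a <- smooth_to_target(g_a, x, t_a, 100, dv_units = TRUE)$iterations
  n_b <- smooth_to_target(g_b, x, t_b, 100, dv_units = TRUE)$iterations
  expect_lte(abs(n_a - n_b), 1L)
})

test_that("smoothness reports serialize with the flat-field sentinel as a flag", {
  g <- build_neighbor_graph(sphere3)
  x <- nn_smooth(g, with_seed_test(11, stats::rnorm(642)), 4)
  rep <- smoothness_report(g, x, iterations = 4L)
  expect_equal(rep$fwhm_dv_units, rep$fwhm / rep$edge_stats$dv, tolerance = 1e-12)
  path <- withr::local_tempfile(fileext = ".json")
  write_smoothness_report(rep, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$fwhm_mm, rep$fwhm, tolerance = 1e-9)

  flat <- structure(list(fwhm = Inf, fwhm_dv_units = Inf, iterations = 0L,
                         edge_stats = list(dv = 1, var_ds = 0, var_s = 1)),
                    class = "smoothness_report")
  write_smoothness_report(flat, path)
  expect_identical(jsonlite::read_json(path)$fwhm_mm, "flat")
})
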
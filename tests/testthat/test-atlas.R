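make_partition <- function(mesh, n_parts = 3) {
  # bands of latitude: a disjoint, exhaustive parcellation
  z <- mesh$vertices[, 3]
  br <- stats::quantile(z, probs = seq(0, 1, length.out = n_parts + 1))
  br[1] <- -Inf; br[n_parts + 1] <- Inf
  idx <- cut(z, br, labels = FALSE)
  parcellation_masks(stats::setNames(
    lapply(seq_len(n_parts), function(k) idx == k),
    sprintf("band%d", seq_len(n_parts))
  ))
}

test_that("region means decompose the global mean and respect the inclusion mask", {
  cohort <- random_cohort(sphere3, n = 4, seed = 25)
  m <- lsctp_map(cohort, sphere3, 4)
  rois <- make_partition(sphere3, 3)
  tab <- roi_mean_lsctp(m, rois)
  expect_identical(tab$roi, c("band1", "band2", "band3"))
  # weighted combination of part means equals the global mean
  expect_equal(sum(tab$mean * tab$n_vertices) / sum(tab$n_vertices),
               mean(m$mean_r[m$included]), tolerance = 1e-12)
  # whole-mask region reproduces the global mean
  whole <- parcellation_masks(list(all = rep(TRUE, 642)))
  expect_equal(roi_mean_lsctp(m, whole)$mean, mean(m$mean_r[m$included]),
               tolerance = 1e-12)
  # a region disjoint from the inclusion mask is missing, not zero
  m2 <- m
  m2$included[rois$band1] <- FALSE
  t2 <- roi_mean_lsctp(m2, rois)
  expect_true(is.na(t2$mean[1]))
  expect_identical(t2$n_vertices[1], 0L)
  # excluded vertices do not contaminate the remaining means
  m3 <- m
  m3$mean_r[!m3$included] <- 99
  expect_equal(roi_mean_lsctp(m3, rois)$mean, tab$mean, tolerance = 1e-12)
})

test_that("region means are invariant to mask order and support the z scale", {
  cohort <- random_cohort(sphere3, n = 4, seed = 26)
  m <- lsctp_map(cohort, sphere3, 4)
  rois <- make_partition(sphere3, 3)
  rev_rois <- parcellation_masks(rev(unclass(rois)))
  a <- roi_mean_lsctp(m, rois)
  b <- roi_mean_lsctp(m, rev_rois)
  expect_equal(a$mean, rev(b$mean), tolerance = 1e-12)
  z <- roi_mean_lsctp(m, rois, scale = "z")
  expect_equal(z$mean[1], mean(atanh(m$mean_r[rois$band1 & m$included])),
               tolerance = 1e-9)
})

test_that("null region baselines grand-average the per-replicate means", {
  sim <- simulate_cohort(sphere3, n_subjects = 5, seed = 27)
  rois <- make_partition(sphere3, 3)
  reps <- lapply(1:4, function(r) {
    shuffled <- unclass(sim$cohort)
    for (s in seq_len(nrow(shuffled))) {  # independent shuffle per subject
      shuffled[s, ] <- shuffle_within_mask(shuffled[s, ], rep(TRUE, 642),
                                           seed = r * 100 + s)
    }
    lsctp_map(cohort_thickness(shuffled), sphere3, 8)
  })
  tab <- null_roi_means(reps, rois)
  expect_identical(nrow(tab), 3L)
  expect_identical(tab$n_replicates, rep(4L, 3))
  # grand mean equals the mean of per-replicate region means
  per_rep <- vapply(reps, function(m) roi_mean_lsctp(m, rois)$mean[2], numeric(1))
  expect_equal(tab$grand_mean[2], mean(per_rep), tolerance = 1e-12)
  # chance similarity per region is extraordinarily low: near zero within
  # sampling error plus the small-sample window bias (order 1/window size)
  expect_true(all(abs(tab$grand_mean) <
                    3 * pmax(tab$sd_across_replicates / sqrt(4), 0.005) + 0.01))
  # single replicate: grand mean is that replicate's mean
  one <- null_roi_means(reps[1], rois)
  expect_equal(one$grand_mean, roi_mean_lsctp(reps[[1]], rois)$mean,
               tolerance = 1e-12)
})

test_that("region ranks flag exactly the perturbed regions", {
  base <- data.frame(roi = c("a", "b", "c", "d"), mean = c(0.4, 0.3, 0.2, 0.1),
                     n_vertices = 10L)
  tabs <- list(d4 = base, d8 = base, d16 = base)
  rk <- rank_by_window(tabs)
  expect_identical(rk$n_unstable, 0L)
  expect_equal(unname(rk$ranks[, "d8"]), 1:4)

  swapped <- base
  swapped$mean <- c(0.3, 0.4, 0.2, 0.1)  # a and b trade places
  rk2 <- rank_by_window(list(d4 = base, d8 = swapped))
  expect_identical(sort(rk2$unstable_rois), c("a", "b"))
  expect_identical(rk2$n_unstable, 2L)

  tied <- base
  tied$mean <- c(0.4, 0.4, 0.2, 0.1)
  rk3 <- rank_by_window(list(d4 = tied))
  expect_equal(unname(rk3$ranks[1:2, 1]), c(1.5, 1.5))
})

test_that("stronger shared profiles produce higher region means in the recovered order", {
  # five strength levels on disjoint caps centered at original icosahedron
  # vertices (pairwise >= 8 mm apart, caps of radius 3.5 mm cannot touch)
  strengths <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  regions <- Map(function(ctr, rho) list(mask = cap_mask(sphere3, ctr, 3.5), rho = rho),
                 1:5, strengths)
  sim <- simulate_cohort(sphere3, n_subjects = 42, regions = regions, seed = 33)
  m <- lsctp_map(sim$cohort, sphere3, 4)
  rois <- parcellation_masks(stats::setNames(lapply(regions, `[[`, "mask"),
                                             sprintf("r%g", strengths)))
  tab <- roi_mean_lsctp(m, rois)
  expect_gte(stats::cor(tab$mean, strengths, method = "spearman"), 0.9)
  expect_gt(tab$mean[5], tab$mean[1])
})

test_that("parcellations load from TSV and reject bad indices", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# vertex\troi (0-based)", "0\tA", "1\tA", "5\tB"), path)
  rois <- read_parcellation_tsv(path, 12)
  expect_identical(names(rois), c("A", "B"))
  expect_identical(which(rois$A), c(1L, 2L))
  expect_identical(which(rois$B), 6L)
  writeLines(c("12\tA"), path)
  expect_error(read_parcellation_tsv(path, 12), class = "lsctp_bounds_error")
  expect_error(parcellation_masks(list(a = c(TRUE, FALSE), b = TRUE)),
               class = "lsctp_dimension_error")
  expect_error(parcellation_masks(list(c(TRUE, FALSE))), class = "lsctp_parameter_error")
})

test_that("long-format summaries stack one row per diameter and region", {
  cohort <- random_cohort(sphere3, n = 4, seed = 29)
  sweep <- lsctp_sweep(cohort, sphere3, c(4, 6))
  rois <- make_partition(sphere3, 2)
  long <- roi_summary_long(sweep, rois)
  expect_identical(nrow(long), 4L)
  expect_setequal(long$diameter_mm, c(4, 6))
  expect_equal(long$mean[long$diameter_mm == 6],
               roi_mean_lsctp(sweep$d6, rois)$mean, tolerance = 1e-12)
})
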
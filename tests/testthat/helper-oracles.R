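# Shared fixtures and independent brute-force oracles. The oracles use
# plain nested loops and stats::cor / explicit formulas, never the code
# paths they check.

ico <- make_icosphere(0, 1)
ico1 <- make_icosphere(1, 1)           # 42 vertices
sphere3 <- make_icosphere(3, 7.6)      # 642 vertices, dv ~ 1.14 mm

# Naive per-vertex, per-pair LSCTP: explicit distance scan for the window,
# stats::cor per subject pair, hand-written Fisher average.
oracle_lsctp <- function(cohort, mesh, diameter) {
  nv <- nrow(mesh$vertices)
  n <- nrow(cohort)
  mean_r <- rep(NA_real_, nv)
  included <- rep(FALSE, nv)
  for (v in seq_len(nv)) {
    d <- sqrt(colSums((t(mesh$vertices) - mesh$vertices[v, ])^2))
    w <- which(d <= diameter / 2)
    if (length(w) < 3) next
    if (any(cohort[, w] == 0)) next
    ok <- TRUE
    zs <- c()
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (stats::sd(cohort[i, w]) == 0 || stats::sd(cohort[j, w]) == 0) {
          ok <- FALSE
          break
        }
        r <- stats::cor(cohort[i, w], cohort[j, w])
        r <- max(min(r, 1 - 1e-7), -(1 - 1e-7))
        zs <- c(zs, atanh(r))
      }
      if (!ok) break
    }
    if (!ok) next
    mean_r[v] <- tanh(mean(zs))
    included[v] <- TRUE
  }
  list(mean_r = mean_r, included = included)
}

# Edge statistics by direct enumeration over the faces.
oracle_edge_stats <- function(mesh, values, mask = NULL) {
  mask <- if (is.null(mask)) rep(TRUE, nrow(mesh$vertices)) else mask
  seen <- c()
  lens <- c()
  diffs <- c()
  for (f in seq_len(nrow(mesh$faces))) {
    tri <- mesh$faces[f, ]
    for (p in list(c(1, 2), c(2, 3), c(1, 3))) {
      a <- min(tri[p]); b <- max(tri[p])
      key <- paste(a, b)
      if (key %in% seen) next
      seen <- c(seen, key)
      if (mask[a] && mask[b]) {
        lens <- c(lens, sqrt(sum((mesh$vertices[a, ] - mesh$vertices[b, ])^2)))
        diffs <- c(diffs, values[a] - values[b])
      }
    }
  }
  pv <- function(x) mean((x - mean(x))^2)
  list(dv = mean(lens), var_ds = pv(diffs), var_s = pv(values[mask]),
       n_edges = length(lens))
}

# Dense averaging-matrix oracle for nearest-neighbor smoothing.
oracle_smooth_matrix <- function(mesh) {
  nv <- nrow(mesh$vertices)
  A <- diag(nv)
  for (f in seq_len(nrow(mesh$faces))) {
    tri <- mesh$faces[f, ]
    for (p in list(c(1, 2), c(2, 3), c(1, 3))) {
      A[tri[p][1], tri[p][2]] <- 1
      A[tri[p][2], tri[p][1]] <- 1
    }
  }
  A / rowSums(A)
}

# Cohort of identical copies of one smooth nonconstant map.
identical_cohort <- function(mesh, n = 4, seed = 1) {
  vals <- with_seed_test(seed, stats::rnorm(nrow(mesh$vertices)))
  g <- build_neighbor_graph(mesh)
  vals <- nn_smooth(g, vals, 2) + 3
  cohort_thickness(matrix(rep(vals, each = n), nrow = n))
}

random_cohort <- function(mesh, n = 4, seed = 1) {
  nv <- nrow(mesh$vertices)
  cohort_thickness(with_seed_test(seed, matrix(stats::runif(n * nv, 1, 4), nrow = n)))
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
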
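# Internal helpers: typed conditions, seed management, population variance.

#' @keywords internal
lsctp_abort <- function(msg, class) {
  stop(structure(
    class = c(class, "lsctp_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

lsctp_warn <- function(msg, class) {
  warning(structure(
    class = c(class, "lsctp_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Splittable counter scheme: independent, reproducible streams per
# (replicate, subject) pair without collisions for subject < 1000.
derive_seed <- function(base_seed, replicate, subject) {
  s <- (as.double(base_seed) %% 65521) * 30011 +
    as.double(replicate) * 1009 + as.double(subject)
  as.integer(s %% 2147483647L)
}

# Population (divide-by-n) variance; the n/(n-1) convention would cancel in
# the FWHM ratio only if applied to numerator and denominator alike, so one
# convention is fixed here and used everywhere.
pop_var <- function(x) {
  m <- mean(x)
  mean((x - m)^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
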
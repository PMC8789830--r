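# Shared fixtures, generated in code.

# small phantom series reused across tests (memoised)
tiny_series <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- phantom_spec(grid_size = c(32L, 32L, 16L), n_vessels = 4L,
                           seed = 7L)
      cache <<- phantom_series(spec, n_repeats = 8L)
    }
    cache
  }
})

# deterministic 64x64 diagonal checkerboard (8-pixel bands, values 0.2/0.8)
checkerboard64 <- function() {
  cb <- (outer(0:63, 0:63, "+") %/% 8) %% 2
  ifelse(cb == 0, 0.2, 0.8)
}

# central-difference gradient of a scalar function of a vector
num_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- x[i] + eps
    xm[i] <- x[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# small training-pair fixture
tiny_pairs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- phantom_spec(grid_size = c(32L, 32L, 24L), n_vessels = 5L,
                           seed = 21L)
      series <- phantom_series(spec, n_repeats = 8L)
      cache <<- make_pairs(series, 2L, seed = 21L,
                           min_vessel_fraction = 0.02)
    }
    cache
  }
})
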
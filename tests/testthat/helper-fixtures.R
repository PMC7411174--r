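# Shared fixtures, built once per test run. Small grids keep the suite
# fast; the phantom geometry is the same nested-ellipsoid design as the
# package default.

.fixture_cache <- new.env(parent = emptyenv())

with_cache <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, expr, envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

small_grid <- c(16L, 16L, 8L)

# Noiseless, confound-free subject at the default phantom geometry (the
# small grid cannot resolve the boundary shells around the WM core, so
# tissue-recovery assertions use the default grid).
clean_subject <- function() {
  with_cache("clean_subject", {
    p <- ground_truth_params(noise_sd_asl = 0, noise_sd_bold = 0, seed = 42)
    simulate_subject(p, capno_noise_sd = 0)
  })
}

clean_fit <- function() {
  with_cache("clean_fit", process_subject(clean_subject(), make_maps = TRUE))
}

# Subject with generator-default noise.
noisy_subject <- function(seed = 42, ...) {
  p <- ground_truth_params(seed = seed, ...)
  simulate_subject(p, grid_dims = small_grid)
}

# Brute-force surround subtraction on a 1D sequence: explicit loop over
# time, the independent oracle for the vectorized implementation.
surround_subtract_loop <- function(x, first = "control") {
  n <- length(x)
  sgn <- rep(if (first == "control") c(1, -1) else c(-1, 1),
             length.out = n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- if (i == 1) x[2] else if (i == n) x[n - 1] else
      (x[i - 1] + x[i + 1]) / 2
    out[i] <- (x[i] - nb) * sgn[i]
  }
  out
}

# Brute-force OLS via the normal equations.
ols_oracle <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}
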
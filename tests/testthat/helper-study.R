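# Shared fixtures, built in code. The 80 MeV desk-scale study (small lateral
# phantom, 0.5 mm depth bins, 15-75 min acquisition window) is expensive
# enough to build once and memoise across test files.

.study_cache <- new.env(parent = emptyenv())

demo_study_80 <- function() {
  if (!is.null(.study_cache$s80)) return(.study_cache$s80)
  phantom <- phantom_spec(c(20, 20, 60), c(5, 5, 0.5))
  beam <- suppressWarnings(beam_spec(80))
  yields <- yield_map_3d(beam, phantom)
  series <- build_frames(yields, schedule = frame_schedule(60, 60, t0_s = 15 * 60))
  fits <- fit_series(series)
  bragg <- find_peak(depth_dose_profile(80))$depth_mm
  .study_cache$s80 <- list(phantom = phantom, beam = beam, yields = yields,
                           series = series, fits = fits, bragg_mm = bragg)
  .study_cache$s80
}

# Best single-component non-negative fit by exhaustive search over the grid:
# the independent oracle that bounds the NNLS residual from above.
brute_force_single <- function(tac, basis) {
  best <- sqrt(sum(tac^2))  # the zero solution
  for (j in seq_len(ncol(basis))) {
    b <- basis[, j]
    a <- max(0, sum(tac * b) / sum(b * b))
    best <- min(best, sqrt(sum((tac - a * b)^2)))
  }
  best
}

# Textbook natural cubic spline: solve the tridiagonal system for the second
# derivatives (natural boundary conditions) and evaluate piecewise.
natural_spline_eval <- function(x, y, xout) {
  n <- length(x)
  h <- diff(x)
  # interior equations: h[i-1] M[i-1] + 2(h[i-1]+h[i]) M[i] + h[i] M[i+1] = rhs
  A <- matrix(0, n, n)
  rhs <- numeric(n)
  A[1, 1] <- 1; A[n, n] <- 1
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- h[i - 1]
    A[i, i] <- 2 * (h[i - 1] + h[i])
    A[i, i + 1] <- h[i]
    rhs[i] <- 6 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1])
  }
  M <- solve(A, rhs)
  vapply(xout, function(xq) {
    i <- max(1, min(n - 1, findInterval(xq, x)))
    dx <- xq - x[i]
    hi <- h[i]
    y[i] +
      dx * ((y[i + 1] - y[i]) / hi - hi / 6 * (2 * M[i] + M[i + 1])) +
      dx^2 * M[i] / 2 +
      dx^3 * (M[i + 1] - M[i]) / (6 * hi)
  }, 0)
}
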
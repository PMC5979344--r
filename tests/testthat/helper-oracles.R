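# Independent oracles used across the suite. Each is deliberately written in
# the most literal way possible (explicit loops, textbook formulas) so it
# shares no code path with the implementation it checks.

# Exhaustive per-pixel local-maximum scan with the same dominance/tie rule as
# the detection contract: strictly greater than every neighbor within
# Chebyshev distance `radius`, equal values resolved in favor of the
# lexicographically smaller (row, col).
bf_nms <- function(v, threshold, radius) {
  nr <- nrow(v); nc <- ncol(v)
  hits <- list()
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (v[r, c] < threshold) next
      ok <- TRUE
      for (dr in -radius:radius) {
        for (dc in -radius:radius) {
          if (dr == 0 && dc == 0) next
          rr <- r + dr; cc <- c + dc
          if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
          if (v[rr, cc] > v[r, c]) { ok <- FALSE; break }
          if (v[rr, cc] == v[r, c]) {
            neighbor_earlier <- (rr < r) || (rr == r && cc < c)
            if (neighbor_earlier) { ok <- FALSE; break }
          }
        }
        if (!ok) break
      }
      if (ok) hits[[length(hits) + 1]] <- c(row = r - 1L, col = c - 1L)
    }
  }
  if (length(hits) == 0) return(matrix(integer(), 0, 2,
                                       dimnames = list(NULL, c("row", "col"))))
  do.call(rbind, hits)
}

# Naive double-loop Parzen cost function, exactly as the formula prints.
bf_cost_function <- function(moving, fixed, d, sigma) {
  total <- 0
  for (j in seq_len(nrow(moving))) {
    for (i in seq_len(nrow(fixed))) {
      dd <- (moving[j, 1] + d[1] - fixed[i, 1])^2 +
        (moving[j, 2] + d[2] - fixed[i, 2])^2
      total <- total + exp(-dd / (2 * sigma^2)) / (2 * pi * sigma^2)
    }
  }
  total
}

# 2-D numerical integration of the unit Gaussian over one pixel.
gauss_pixel_integral <- function(x_lo, x_hi, y_lo, y_hi, x0, y0, s) {
  pracma::integral2(function(x, y)
    exp(-((x - x0)^2 + (y - y0)^2) / (2 * s^2)) / (2 * pi * s^2),
    x_lo, x_hi, y_lo, y_hi, reltol = 1e-12)$Q
}

# Discretized penalized least squares: minimize
#   p * sum (y_i - f(t_i))^2 + (1 - p) * int f''^2
# with f on a fine uniform grid and the integral by second differences.
# Independent route to the smoothing-spline solution (up to grid error).
qp_spline <- function(t, y, p, grid_step = 0.05) {
  g <- seq(min(t), max(t), by = grid_step)
  stopifnot(all(apply(abs(outer(t, g, "-")), 1, min) < 1e-9))
  m <- length(g)
  S <- matrix(0, length(t), m)
  for (i in seq_along(t)) S[i, which.min(abs(g - t[i]))] <- 1
  D <- matrix(0, m - 2, m)
  for (j in seq_len(m - 2)) D[j, j:(j + 2)] <- c(1, -2, 1) / grid_step^2
  A <- p * crossprod(S) + (1 - p) * grid_step * crossprod(D)
  f <- solve(A, p * crossprod(S, y))
  list(grid = g, fit = as.numeric(f), at_t = as.numeric(S %*% f))
}

# Build a fit window directly from the forward model.
model_window <- function(n = 9, x0, y0, N, b, s, a = 100) {
  structure(list(pixels = erf_model(n, n, x0, y0, N, b, s, a),
                 origin = c(col = 0L, row = 0L)),
            class = "fit_window")
}

expect_no_na <- function(x) expect_false(anyNA(x))
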
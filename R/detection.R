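#' Separable Gaussian pre-smoother
#'
#' Truncated (radius `ceiling(3*sigma)`) Gaussian kernel applied along rows
#' and columns with per-pixel renormalization at the borders, so constants are
#' preserved exactly everywhere. Constant preservation is what makes candidate
#' detection invariant under adding an offset to the frame and the threshold.
#'
#' @param frame Numeric matrix.
#' @param sigma Kernel standard deviation in pixels; 0 returns the input.
#' @return Smoothed matrix of the same size.
#' @export
gaussian_smooth <- function(frame, sigma = 1) {
  if (sigma <= 0) return(frame)
  smoother <- function(n) {
    r <- ceiling(3 * sigma)
    w <- exp(-(-r:r)^2 / (2 * sigma^2))
    s <- matrix(0, n, n)
    for (k in -r:r) {
      idx <- seq_len(n)
      j <- idx + k
      ok <- j >= 1 & j <= n
      s[cbind(idx[ok], j[ok])] <- s[cbind(idx[ok], j[ok])] + w[k + r + 1]
    }
    s / rowSums(s)
  }
  smoother(nrow(frame)) %*% frame %*% t(smoother(ncol(frame)))
}

#' Candidate molecule positions by thresholded non-maximum suppression
#'
#' After optional Gaussian pre-smoothing, a pixel is a candidate when its
#' smoothed value is at least `threshold` and it dominates every neighbor
#' within Chebyshev distance `radius`: strictly greater, or equal with the
#' candidate earlier in (row, col) lexicographic order (so exactly one pixel
#' of an equal-valued plateau survives, deterministically).
#'
#' @param frame Numeric matrix of photon counts for one frame.
#' @param threshold Minimum smoothed peak value (photons), > 0.
#' @param radius Suppression radius in pixels (Chebyshev), >= 1.
#' @param presmooth_sigma Gaussian pre-smoothing sigma in pixels (0 = none).
#' @return A tibble `row, col, peak` ordered by (row, col); pixel indices are
#'   0-based (see [image_stack()] for the coordinate convention).
#' @examples
#' f <- matrix(0, 11, 11); f[6, 6] <- 100
#' find_candidates(f, threshold = 50, radius = 3, presmooth_sigma = 0)
#' @export
find_candidates <- function(frame, threshold, radius = 3, presmooth_sigma = 1) {
  if (!is.matrix(frame) || length(frame) == 0) abort("`frame` must be a non-empty matrix.")
  if (radius < 1) abort("`radius` must be >= 1.")
  if (threshold <= 0) abort("`threshold` must be > 0.")
  if (radius >= max(dim(frame))) abort("`radius` larger than the frame extent.")
  v <- gaussian_smooth(frame, presmooth_sigma)
  nr <- nrow(v); nc <- ncol(v)
  keep <- v >= threshold
  for (dy in -radius:radius) {
    for (dx in -radius:radius) {
      if (dy == 0 && dx == 0) next
      if (!any(keep)) break
      # neighbor value at (row+dy, col+dx); outside the frame counts as -Inf
      sh <- matrix(-Inf, nr, nc)
      r_src <- max(1, 1 + dy):min(nr, nr + dy)
      c_src <- max(1, 1 + dx):min(nc, nc + dx)
      sh[r_src - dy, c_src - dx] <- v[r_src, c_src]
      # the neighbor is lexicographically later iff dy > 0 or (dy == 0, dx > 0)
      later <- dy > 0 || (dy == 0 && dx > 0)
      keep <- keep & (v > sh | (later & v == sh))
    }
  }
  idx <- which(keep, arr.ind = TRUE)
  out <- tibble(row = unname(idx[, 1]) - 1L, col = unname(idx[, 2]) - 1L,
                peak = unname(v[idx]))
  dplyr::arrange(out, .data$row, .data$col)
}
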
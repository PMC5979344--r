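#' Pixel-integrated Gaussian (error-function) PSF model
#'
#' Expected photon count of each pixel of a window under a symmetric 2-D
#' Gaussian PSF of width `s` (sigma, nm) integrated over the square pixels,
#' plus a flat background. With pixel edge length `a` (nm) and `x_k = k * a`
#' the left edge of (0-based) pixel column k,
#' \deqn{E[k,l] = b + N \, \Delta E_x(k) \, \Delta E_y(l)}
#' \deqn{\Delta E_x(k) = \tfrac12\left[\mathrm{erf}\!\left(\frac{x_k + a - x_0}{\sqrt2 s}\right)
#'   - \mathrm{erf}\!\left(\frac{x_k - x_0}{\sqrt2 s}\right)\right]}
#' and analogously in y. The sum of \eqn{\Delta E_x} over all columns never
#' exceeds 1, so `N` is the total expected photon count of the molecule.
#'
#' @param ncol_px,nrow_px Window size in pixels.
#' @param x0,y0 Molecule position (nm) in the window's coordinate frame
#'   (origin at the outer corner of the window's pixel (0,0)).
#' @param N Expected total photons (>= 0).
#' @param b Background photons per pixel.
#' @param s PSF Gaussian sigma (nm), > 0.
#' @param a Pixel size (nm), > 0.
#' @return `nrow_px` x `ncol_px` matrix of expected photons.
#' @export
erf_model <- function(ncol_px, nrow_px, x0, y0, N, b, s, a) {
  if (s <= 0) abort("`s` must be > 0.")
  if (a <= 0) abort("`a` must be > 0.")
  edges_x <- (0:ncol_px) * a
  edges_y <- (0:nrow_px) * a
  px <- pnorm((edges_x - x0) / s)
  py <- pnorm((edges_y - y0) / s)
  dex <- diff(px)
  dey <- diff(py)
  b + N * outer(dey, dex)
}

#' Positional accuracy of a fitted localization
#'
#' Predicted standard deviation (nm) of the fitted molecule position from
#' photon count `N`, PSF width `s`, pixel size `a` and the background
#' variability `b_var` (standard deviation, in photons, of the residual
#' background — not its mean level):
#' \deqn{\sigma_{loc}^2 = \frac{s^2 + a^2/12}{N} + \frac{8\pi s^4 b_{var}^2}{a^2 N^2}}
#'
#' @param N Photon count, > 0.
#' @param b_var Background variability (photons), >= 0.
#' @param s PSF sigma (nm).
#' @param a Pixel size (nm).
#' @return sigma_loc in nm.
#' @examples
#' positional_accuracy(1000, 3, 150, 100)
#' @export
positional_accuracy <- function(N, b_var, s, a) {
  if (any(N <= 0)) abort("`N` must be > 0.")
  if (any(b_var < 0)) abort("`b_var` must be >= 0.")
  sqrt((s^2 + a^2 / 12) / N + 8 * pi * s^4 * b_var^2 / (a^2 * N^2))
}

#' Cut a square fit window around a candidate
#'
#' @param frame Photon matrix of one frame.
#' @param col,row 0-based pixel indices of the candidate.
#' @param w Window half-width in pixels; the window is (2w+1) x (2w+1).
#' @return A `fit_window` (list with `pixels`, `origin` = 0-based (col, row)
#'   of the top-left pixel) or `NULL` when the window would leave the frame.
#' @export
cut_window <- function(frame, col, row, w = 4) {
  nr <- nrow(frame); nc <- ncol(frame)
  if (row - w < 0 || col - w < 0 || row + w > nr - 1 || col + w > nc - 1)
    return(NULL)
  structure(
    list(pixels = frame[(row - w):(row + w) + 1L, (col - w):(col + w) + 1L],
         origin = c(col = col - w, row = row - w)),
    class = "fit_window"
  )
}

border_ring <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  c(m[1, ], m[nr, ], m[2:(nr - 1), 1], m[2:(nr - 1), nc])
}

#' Background variability of a fitted window
#'
#' Standard deviation of (data - model) over the one-pixel border ring of the
#' fit window; feeds the background term of [positional_accuracy()].
#'
#' @param win A `fit_window` (see [cut_window()]).
#' @param fit A `psf_fit` from [fit_spot()].
#' @return Standard deviation in photons.
#' @export
background_variability <- function(win, fit) {
  px <- win$pixels
  if (nrow(px) < 3 || ncol(px) < 3) abort("window too small for a border ring.")
  a <- fit$pixel_size_nm
  model <- erf_model(ncol(px), nrow(px), fit$x_local_nm, fit$y_local_nm,
                     fit$photons, fit$background, fit$psf_width_nm, a)
  sd(border_ring(px - model))
}

#' Fit one spot with the integrated-Gaussian PSF model
#'
#' Unweighted least squares over (x0, y0, N, b, s), solved with a
#' trust-region least-squares routine (Levenberg-Marquardt). Initialization:
#' position at the candidate pixel center, background at the window-border
#' median, N at (window sum - b * area), s = 1.3 pixels. Fits that end on the
#' width bounds `s in [0.5 a, 4 a]`, lose the position out of the window, or
#' fail the optimizer are flagged `converged = FALSE`.
#'
#' @param win A `fit_window` from [cut_window()].
#' @param cam A [camera_model()] (supplies the pixel size).
#' @param max_iter Maximum optimizer iterations.
#' @param ftol Relative objective-decrease tolerance for convergence.
#' @return A `psf_fit` list: `x_nm`, `y_nm` (frame coordinates), `photons`,
#'   `background`, `psf_width_nm`, `residual_norm`, `converged`,
#'   `background_variability`, `accuracy_nm`, plus window-local coordinates.
#' @export
fit_spot <- function(win, cam, max_iter = 200, ftol = 1e-8) {
  stopifnot(inherits(win, "fit_window"), inherits(cam, "camera_model"))
  px <- win$pixels
  n <- nrow(px)
  if (n != ncol(px) || n %% 2 == 0) abort("fit window must be square with odd edge.")
  a <- cam$pixel_size_nm

  out <- list(
    x_nm = NA_real_, y_nm = NA_real_, photons = NA_real_, background = NA_real_,
    psf_width_nm = NA_real_, residual_norm = NA_real_, converged = FALSE,
    background_variability = NA_real_, accuracy_nm = NA_real_,
    x_local_nm = NA_real_, y_local_nm = NA_real_, pixel_size_nm = a,
    origin = win$origin
  )
  class(out) <- "psf_fit"
  if (sd(px) == 0) return(out)  # flat window: nothing to fit

  b0 <- median(border_ring(px))
  N0 <- max(sum(px) - b0 * n^2, 1)
  c0 <- (n - 1) / 2          # center pixel (0-based)
  start <- c(x0 = (c0 + 0.5) * a, y0 = (c0 + 0.5) * a, N = N0, b = max(b0, 0),
             s = 1.3 * a)
  lower <- c(0, 0, 0, 0, 0.5 * a)
  upper <- c(n * a, n * a, Inf, Inf, 4 * a)

  resid_fun <- function(p) {
    as.vector(px - erf_model(n, n, p[1], p[2], p[3], p[4], p[5], a))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                       fn = resid_fun,
                       control = minpack.lm::nls.lm.control(
                         maxiter = max_iter, ftol = ftol, ptol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit)) return(out)

  p <- fit$par
  out$x_local_nm <- p[[1]]; out$y_local_nm <- p[[2]]
  out$x_nm <- win$origin[["col"]] * a + p[[1]]
  out$y_nm <- win$origin[["row"]] * a + p[[2]]
  out$photons <- p[[3]]; out$background <- p[[4]]; out$psf_width_nm <- p[[5]]
  out$residual_norm <- sqrt(sum(fit$fvec^2))

  eps <- 1e-6 * a
  ok <- fit$info %in% 1:4 &&
    p[[3]] > 0 &&
    p[[5]] > lower[5] + eps && p[[5]] < upper[5] - eps &&
    p[[1]] > 0 && p[[1]] < n * a && p[[2]] > 0 && p[[2]] < n * a
  out$converged <- isTRUE(ok)
  if (out$converged) {
    out$background_variability <- background_variability(win, out)
    out$accuracy_nm <- positional_accuracy(out$photons, out$background_variability,
                                           out$psf_width_nm, a)
  }
  out
}

#' @export
print.psf_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<psf_fit> not converged\n")
  } else {
    cat(sprintf("<psf_fit> x %.1f nm, y %.1f nm, N %.0f, b %.2f, s %.1f nm, sigma_loc %.2f nm\n",
                x$x_nm, x$y_nm, x$photons, x$background, x$psf_width_nm, x$accuracy_nm))
  }
  invisible(x)
}

#' @method tidy psf_fit
#' @export
tidy.psf_fit <- function(x, ...) {
  tibble(term = c("x_nm", "y_nm", "photons", "background", "psf_width_nm"),
         estimate = c(x$x_nm, x$y_nm, x$photons, x$background, x$psf_width_nm))
}

#' @method glance psf_fit
#' @export
glance.psf_fit <- function(x, ...) {
  tibble(converged = x$converged, residual_norm = x$residual_norm,
         accuracy_nm = x$accuracy_nm,
         background_variability = x$background_variability)
}
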
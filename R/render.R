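#' Render a super-resolution image from localizations
#'
#' Each localization is drawn as a symmetric 2-D Gaussian centered at its
#' fitted position with sigma equal to its positional accuracy, integrated
#' over the output pixels (so blob mass is exact) and truncated at 5 sigma.
#' In `"unit"` mode every blob integrates to 1 — brighter areas then read
#' directly as higher localization density; in `"photons"` mode each blob
#' integrates to the molecule's photon count.
#'
#' @param set Localization tibble with `x_nm, y_nm, uncertainty_nm` (and
#'   `photons` for photons mode).
#' @param out_pixel_size Output pixel size in nm (default 10).
#' @param extent Bounding box `c(xmin, xmax, ymin, ymax)` in nm; default:
#'   data range padded by 3x the largest accuracy.
#' @param amplitude_mode "unit" or "photons".
#' @return An `smlm_image`: a numeric matrix (rows = y) with attributes
#'   `pixel_size_nm` and `origin_nm` (the (xmin, ymin) corner).
#' @export
render <- function(set, out_pixel_size = 10, extent = NULL,
                   amplitude_mode = c("unit", "photons")) {
  amplitude_mode <- match.arg(amplitude_mode)
  if (out_pixel_size <= 0) abort("`out_pixel_size` must be > 0.")
  empty <- is.null(set) || nrow(set) == 0
  if (!empty) {
    validate_localizations(set, require_uncertainty = TRUE)
    if (any(set$uncertainty_nm <= 0)) abort("every localization needs accuracy > 0.")
  }
  if (is.null(extent)) {
    if (empty) abort("`extent` is required for an empty set.")
    pad <- 3 * max(set$uncertainty_nm)
    extent <- c(min(set$x_nm) - pad, max(set$x_nm) + pad,
                min(set$y_nm) - pad, max(set$y_nm) + pad)
  }
  px <- out_pixel_size
  ncol_px <- max(1L, ceiling((extent[2] - extent[1]) / px))
  nrow_px <- max(1L, ceiling((extent[4] - extent[3]) / px))
  img <- matrix(0, nrow_px, ncol_px)
  if (!empty) {
    amp <- if (amplitude_mode == "photons") set$photons else rep(1, nrow(set))
    x0 <- extent[1]; y0 <- extent[3]
    for (i in seq_len(nrow(set))) {
      s <- set$uncertainty_nm[i]
      cx <- set$x_nm[i] - x0
      cy <- set$y_nm[i] - y0
      r <- 5 * s
      c_lo <- max(0L, floor((cx - r) / px)); c_hi <- min(ncol_px - 1L, floor((cx + r) / px))
      r_lo <- max(0L, floor((cy - r) / px)); r_hi <- min(nrow_px - 1L, floor((cy + r) / px))
      if (c_lo > c_hi || r_lo > r_hi) next
      ex <- (c_lo:(c_hi + 1L)) * px
      ey <- (r_lo:(r_hi + 1L)) * px
      dx <- diff(pnorm((ex - cx) / s))
      dy <- diff(pnorm((ey - cy) / s))
      img[(r_lo:r_hi) + 1L, (c_lo:c_hi) + 1L] <-
        img[(r_lo:r_hi) + 1L, (c_lo:c_hi) + 1L] + amp[i] * outer(dy, dx)
    }
  }
  structure(img, class = c("smlm_image", "matrix", "array"),
            pixel_size_nm = px, origin_nm = c(extent[1], extent[3]),
            amplitude_mode = amplitude_mode)
}

#' @export
print.smlm_image <- function(x, ...) {
  cat(sprintf("<smlm_image> %d x %d px at %g nm/px, total intensity %.4g\n",
              nrow(x), ncol(x), attr(x, "pixel_size_nm"), sum(x)))
  invisible(x)
}

#' @method autoplot smlm_image
#' @export
autoplot.smlm_image <- function(object, trans = "sqrt", ...) {
  px <- attr(object, "pixel_size_nm")
  org <- attr(object, "origin_nm")
  df <- expand.grid(row = seq_len(nrow(object)), col = seq_len(ncol(object)))
  df$x_nm <- org[1] + (df$col - 0.5) * px
  df$y_nm <- org[2] + (df$row - 0.5) * px
  df$intensity <- unclass(object)[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_nm, y = .data$y_nm,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(trans = trans) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)", fill = "intensity")
}

#' Write / read a rendered image as 32-bit float TIFF
#'
#' Float TIFF samples are stored normalized to [0, 1]; the absolute scale
#' (the maximum intensity) and the geometry go into a YAML sidecar
#' `<path>.yaml` so `read_render()` restores the image exactly.
#'
#' @param img An `smlm_image` from [render()].
#' @param path Output TIFF path.
#' @return `path` invisibly (write); an `smlm_image` (read).
#' @export
write_render <- function(img, path) {
  stopifnot(inherits(img, "smlm_image"))
  scale <- max(img, 1e-300)
  tiff::writeTIFF(unclass(img) / scale, path, bits.per.sample = 32L,
                  compression = "none")
  yaml::write_yaml(list(scale = scale,
                        pixel_size_nm = attr(img, "pixel_size_nm"),
                        origin_x_nm = attr(img, "origin_nm")[1],
                        origin_y_nm = attr(img, "origin_nm")[2]),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_render
#' @export
read_render <- function(path) {
  m <- tiff::readTIFF(path)
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  structure(m * meta$scale, class = c("smlm_image", "matrix", "array"),
            pixel_size_nm = meta$pixel_size_nm,
            origin_nm = c(meta$origin_x_nm, meta$origin_y_nm))
}
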
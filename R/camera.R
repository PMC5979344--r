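#' EMCCD camera model
#'
#' The ADU-to-photon contract of the acquisition camera. `em_gain` is the
#' effective conversion factor in analog-digital units (ADU) per detected
#' photon, `offset_adu` the constant camera baseline, and `read_noise_adu`
#' the standard deviation of the Gaussian readout noise. The pixel size is
#' the back-projected size in the sample plane.
#'
#' @param pixel_size_nm Length (nm) of one pixel edge in the sample plane.
#' @param em_gain ADU per photon; must be > 0.
#' @param offset_adu ADU baseline added by the camera.
#' @param read_noise_adu Standard deviation (ADU) of read noise; >= 0.
#' @return A `camera_model` object (named list).
#' @examples
#' cam <- camera_model(pixel_size_nm = 100, em_gain = 50, offset_adu = 100)
#' @export
camera_model <- function(pixel_size_nm = 100, em_gain = 50,
                         offset_adu = 100, read_noise_adu = 10) {
  if (!is.numeric(pixel_size_nm) || pixel_size_nm <= 0)
    abort("`pixel_size_nm` must be a positive number.")
  if (!is.numeric(em_gain) || em_gain <= 0)
    abort("`em_gain` must be > 0.")
  if (!is.numeric(read_noise_adu) || read_noise_adu < 0)
    abort("`read_noise_adu` must be >= 0.")
  structure(
    list(pixel_size_nm = as.numeric(pixel_size_nm),
         em_gain = as.numeric(em_gain),
         offset_adu = as.numeric(offset_adu),
         read_noise_adu = as.numeric(read_noise_adu)),
    class = "camera_model"
  )
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf(
    "<camera_model> pixel %g nm, gain %g ADU/photon, offset %g ADU, read noise %g ADU\n",
    x$pixel_size_nm, x$em_gain, x$offset_adu, x$read_noise_adu))
  invisible(x)
}

#' Convert camera counts to photons
#'
#' Applies the affine camera inversion `(ADU - offset) / gain` to every pixel
#' of a stack (or a single frame), clipping negative results to zero so
#' downstream photon counts stay physical.
#'
#' @param stack An [image_stack()] or a numeric matrix of ADU counts.
#' @param cam A [camera_model()].
#' @return The same container with pixel values in expected photons.
#' @examples
#' cam <- camera_model(em_gain = 50, offset_adu = 100)
#' to_photons(matrix(1100, 1, 1), cam)  # 20 photons
#' @export
to_photons <- function(stack, cam) {
  stopifnot(inherits(cam, "camera_model"))
  if (cam$em_gain <= 0) abort("`em_gain` must be > 0.")
  conv <- function(m) pmax((m - cam$offset_adu) / cam$em_gain, 0)
  if (is.matrix(stack)) return(conv(stack))
  stopifnot(inherits(stack, "image_stack"))
  stack$frames <- lapply(stack$frames, conv)
  stack$units <- "photons"
  stack
}
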
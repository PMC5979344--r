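#' Localize molecules in an image stack
#'
#' The per-frame pipeline of the reconstruction: convert counts to photons,
#' propose candidates by thresholded non-maximum suppression, and fit each
#' candidate with the integrated-Gaussian PSF model. Candidates closer than
#' `fit_half_width` pixels to the frame border and non-converged fits are
#' dropped.
#'
#' @param stack An [image_stack()] (ADU or photons).
#' @param cam A [camera_model()].
#' @param threshold Detection threshold in photons *above the frame median*
#'   (the median tracks the background level frame by frame).
#' @param nms_radius Suppression radius (px).
#' @param presmooth_sigma Pre-smoothing sigma (px).
#' @param fit_half_width Fit-window half width w (window is (2w+1) square).
#' @param max_iter Maximum fit iterations per spot.
#' @return A localization tibble with the standard columns `frame, x_nm,
#'   y_nm, photons, background_photons, sigma_psf_nm, uncertainty_nm`.
#' @export
localize_stack <- function(stack, cam, threshold = 30, nms_radius = 3,
                           presmooth_sigma = 1, fit_half_width = 4,
                           max_iter = 200) {
  stopifnot(inherits(stack, "image_stack"), inherits(cam, "camera_model"))
  if (stack$units != "photons") stack <- to_photons(stack, cam)
  res <- vector("list", n_frames(stack))
  for (t in seq_along(stack$frames)) {
    frame <- stack$frames[[t]]
    thr <- median(frame) + threshold
    cands <- find_candidates(frame, threshold = thr, radius = nms_radius,
                             presmooth_sigma = presmooth_sigma)
    if (nrow(cands) == 0) next
    rows <- purrr::pmap(cands, function(row, col, peak) {
      win <- cut_window(frame, col = col, row = row, w = fit_half_width)
      if (is.null(win)) return(NULL)
      fit <- fit_spot(win, cam, max_iter = max_iter)
      if (!fit$converged) return(NULL)
      tibble(frame = t, x_nm = fit$x_nm, y_nm = fit$y_nm,
             photons = fit$photons, background_photons = fit$background,
             sigma_psf_nm = fit$psf_width_nm, uncertainty_nm = fit$accuracy_nm)
    })
    res[[t]] <- dplyr::bind_rows(rows)
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    out <- tibble(frame = integer(), x_nm = double(), y_nm = double(),
                  photons = double(), background_photons = double(),
                  sigma_psf_nm = double(), uncertainty_nm = double())
  }
  out$frame <- as.integer(out$frame)
  out
}
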
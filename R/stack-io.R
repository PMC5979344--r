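#' Time-ordered image stack
#'
#' A light container for a fluorescence movie: a list of equally sized frame
#' matrices plus acquisition metadata. Raw and simulated data are unsigned
#' 16-bit ADU counts; after [to_photons()] the values are expected photons.
#'
#' Coordinate convention used throughout the package: continuous positions in
#' nm with the origin at the outer corner of pixel (0, 0); the center of pixel
#' (col k, row l), both 0-based, is at x = (k + 0.5) * a, y = (l + 0.5) * a
#' where a is the pixel size. x runs along matrix columns, y along rows.
#' Frames are 1-based in all tables.
#'
#' @param frames List of numeric matrices, identical dimensions.
#' @param pixel_size_nm Pixel edge length (nm), > 0.
#' @param exposure_ms Exposure time per frame (ms), > 0.
#' @param units "adu" or "photons".
#' @return An `image_stack` object.
#' @export
image_stack <- function(frames, pixel_size_nm = 100, exposure_ms = 20,
                        units = "adu") {
  if (!is.list(frames) || length(frames) == 0 || !all(vapply(frames, is.matrix, TRUE)))
    abort("`frames` must be a non-empty list of matrices.")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    abort("all frames must share identical height x width.")
  if (pixel_size_nm <= 0) abort("`pixel_size_nm` must be > 0.")
  if (exposure_ms <= 0) abort("`exposure_ms` must be > 0.")
  structure(
    list(frames = frames,
         pixel_size_nm = as.numeric(pixel_size_nm),
         exposure_ms = as.numeric(exposure_ms),
         units = units),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<image_stack> %d frames of %d x %d px (%s), pixel %g nm, exposure %g ms\n",
              length(x$frames), d[1], d[2], x$units, x$pixel_size_nm, x$exposure_ms))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack An [image_stack()].
#' @return Integer frame count.
#' @export
n_frames <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  length(stack$frames)
}

#' Read a multi-page TIFF stack
#'
#' Pages are returned in file order as frames. TIFF tags carry no acquisition
#' metadata in this pipeline; pixel size and exposure come from an optional
#' YAML sidecar (keys `pixel_size_nm`, `exposure_ms`) or the arguments.
#'
#' @param path Path to a multi-page TIFF (16-bit unsigned for raw data).
#' @param pixel_size_nm,exposure_ms Metadata used when no sidecar is present.
#' @param config Optional path to a YAML config (see [read_scope_config()]);
#'   defaults to `<path>.yaml` when that file exists.
#' @return An [image_stack()] with ADU units.
#' @export
read_stack <- function(path, pixel_size_nm = 100, exposure_ms = 20,
                       config = NULL) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) abort(sprintf("not a readable TIFF: %s (%s)",
                                                      path, conditionMessage(e))))
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # collapse accidental extra channel
    storage.mode(p) <- "double"
    p
  })
  if (is.null(config)) {
    side <- paste0(path, ".yaml")
    if (file.exists(side)) config <- side
  }
  if (!is.null(config)) {
    cfg <- read_scope_config(config)
    if (!is.null(cfg$pixel_size_nm)) pixel_size_nm <- cfg$pixel_size_nm
    if (!is.null(cfg$exposure_ms)) exposure_ms <- cfg$exposure_ms
  }
  image_stack(pages, pixel_size_nm = pixel_size_nm, exposure_ms = exposure_ms,
              units = "adu")
}

#' Write a stack as 16-bit unsigned multi-page TIFF
#'
#' Pixel values must lie in [0, 65535]; they are rounded to integers.
#'
#' @param stack An [image_stack()] in ADU units.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  mx <- max(vapply(stack$frames, max, 0))
  mn <- min(vapply(stack$frames, min, 0))
  if (mn < 0 || mx > 65535) abort("pixel values outside the unsigned 16-bit range.")
  pages <- lapply(stack$frames, function(f) round(f) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a flat YAML acquisition config
#'
#' Recognized keys: `pixel_size_nm`, `em_gain`, `offset_adu`,
#' `read_noise_adu`, `exposure_ms`.
#'
#' @param path YAML file path.
#' @return Named list of values present in the file.
#' @export
read_scope_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such config file: %s", path))
  yaml::read_yaml(path)
}

#' Build a camera model from a config list or file
#' @param config Path to a YAML config or a named list.
#' @return A [camera_model()].
#' @export
camera_from_config <- function(config) {
  if (is.character(config)) config <- read_scope_config(config)
  need <- c("pixel_size_nm", "em_gain", "offset_adu")
  miss <- setdiff(need, names(config))
  if (length(miss))
    abort(sprintf("config is missing required key(s): %s", paste(miss, collapse = ", ")))
  camera_model(pixel_size_nm = config$pixel_size_nm,
               em_gain = config$em_gain,
               offset_adu = config$offset_adu,
               read_noise_adu = config$read_noise_adu %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- localization tables ----------------------------------------------------

loc_columns <- c("frame", "x_nm", "y_nm", "photons", "background_photons",
                 "sigma_psf_nm", "uncertainty_nm")

validate_localizations <- function(set, require_uncertainty = FALSE) {
  if (!is.data.frame(set)) abort("localization set must be a data frame.")
  need <- c("frame", "x_nm", "y_nm")
  if (require_uncertainty) need <- c(need, "uncertainty_nm")
  miss <- setdiff(need, names(set))
  if (length(miss))
    abort(sprintf("localization table is missing column(s): %s",
                  paste(miss, collapse = ", ")))
  if (nrow(set) > 0 && any(set$frame < 1))
    abort("`frame` must be >= 1.")
  invisible(set)
}

#' Read / write localization tables
#'
#' The on-disk format is a CSV with the fixed header
#' `frame,x_nm,y_nm,photons,background_photons,sigma_psf_nm,uncertainty_nm`.
#' Positions are written with 0.01 nm precision so independent runs diff
#' cleanly. Extra in-memory columns (e.g. a simulator's emitter id) are
#' dropped on write.
#'
#' @param path CSV file path.
#' @return `read_localizations()` returns a tibble with the seven standard
#'   columns; `write_localizations()` returns `path` invisibly.
#' @export
read_localizations <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(loc_columns, names(tab))
  if (length(miss))
    abort(sprintf("localization CSV is missing column(s): %s",
                  paste(miss, collapse = ", ")))
  tab <- tab[loc_columns]
  if (nrow(tab) > 0) {
    if (!all(vapply(tab, is.numeric, TRUE))) abort("non-numeric cell in localization CSV.")
    if (any(tab$frame < 1)) abort("`frame` must be >= 1.")
  }
  tab$frame <- as.integer(tab$frame)
  tab
}

#' @rdname read_localizations
#' @param set A localization tibble (at least the standard columns).
#' @export
write_localizations <- function(set, path) {
  validate_localizations(set)
  miss <- setdiff(loc_columns, names(set))
  if (length(miss))
    abort(sprintf("localization table is missing column(s): %s",
                  paste(miss, collapse = ", ")))
  out <- set[loc_columns]
  out$frame <- as.integer(out$frame)
  num <- setdiff(loc_columns, "frame")
  out[num] <- lapply(out[num], function(v) round(v, 2))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read / write per-frame drift tracks
#'
#' CSV with header `frame,alpha_nm,beta_nm`: the x (`alpha_nm`) and y
#' (`beta_nm`) drift-compensation shifts added to each localization of that
#' frame.
#'
#' @param path CSV file path.
#' @return A tibble `frame, alpha_nm, beta_nm` (read), or `path` (write).
#' @export
read_drift_track <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(c("frame", "alpha_nm", "beta_nm"), names(tab))
  if (length(miss))
    abort(sprintf("drift CSV is missing column(s): %s", paste(miss, collapse = ", ")))
  tab$frame <- as.integer(tab$frame)
  tab
}

#' @rdname read_drift_track
#' @param track A tibble with columns `frame, alpha_nm, beta_nm`.
#' @export
write_drift_track <- function(track, path) {
  out <- track[c("frame", "alpha_nm", "beta_nm")]
  out$frame <- as.integer(out$frame)
  out$alpha_nm <- round(out$alpha_nm, 2)
  out$beta_nm <- round(out$beta_nm, 2)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
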
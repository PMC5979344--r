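#' Run the full reconstruction pipeline from a config
#'
#' Composes the stages simulate/read -> localize -> drift-correct -> render ->
#' quantify as requested by a YAML config (or an equivalent named list) and
#' writes the artifacts plus a run log with every effective parameter.
#'
#' Config keys:
#' \describe{
#'   \item{camera}{`pixel_size_nm` (required), `em_gain` (required),
#'     `offset_adu` (required), `read_noise_adu`, `exposure_ms`.}
#'   \item{input_stack}{Path to a multi-page TIFF; mutually exclusive with
#'     `simulation`.}
#'   \item{simulation}{Arguments for [scene_spec()] (e.g. `geometry`,
#'     `n_emitters`, `frames`, `drift_nm`, `seed`).}
#'   \item{localize}{Arguments for [localize_stack()].}
#'   \item{drift}{Arguments for [drift_config()]; `enabled: false` skips.}
#'   \item{render}{`out_pixel_size`, `amplitude_mode`.}
#'   \item{quantify}{Optional `line` (x1,y1,x2,y2 nm) for a FWHM fit,
#'     optional `roi` (path to a polygon file, one `x_nm,y_nm` pair per
#'     line) for density, `blinking: true` for event statistics.}
#'   \item{output_dir}{Where artifacts are written.}
#' }
#'
#' @param config Path to a YAML file or a named list.
#' @param output_dir Overrides the config's `output_dir`.
#' @return Invisibly, a list with the in-memory results (`localizations`,
#'   `corrected`, `drift`, `image`, `quantification`, `paths`).
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) abort("`config` must be a YAML path or a named list.")
  out_dir <- output_dir %||% cfg$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (is.null(cfg$camera)) abort("config is missing the `camera` block.")
  cam <- camera_from_config(cfg$camera)

  truth <- NULL
  if (!is.null(cfg$simulation)) {
    sim_args <- cfg$simulation
    if (!is.null(sim_args$drift_nm)) sim_args$drift_nm <- as.numeric(sim_args$drift_nm)
    sim_args$camera <- cam
    spec <- do.call(scene_spec, sim_args)
    sim <- simulate_stack(spec)
    stack <- sim$stack
    truth <- sim$truth
  } else if (!is.null(cfg$input_stack)) {
    stack <- read_stack(cfg$input_stack,
                        pixel_size_nm = cam$pixel_size_nm,
                        exposure_ms = cfg$camera$exposure_ms %||% 20)
  } else {
    abort("config needs either a `simulation` block or an `input_stack` path.")
  }

  loc_args <- cfg$localize %||% list()
  locs <- do.call(localize_stack, c(list(stack = stack, cam = cam), loc_args))
  paths <- list(localizations = file.path(out_dir, "localizations.csv"))
  write_localizations(locs, paths$localizations)

  drift_cfg_args <- cfg$drift %||% list()
  drift_enabled <- !isFALSE(drift_cfg_args$enabled) && nrow(locs) > 0
  drift_cfg_args$enabled <- NULL
  drift_res <- NULL
  corrected <- locs
  if (drift_enabled) {
    dcfg <- do.call(drift_config, drift_cfg_args)
    drift_res <- correct_drift(locs, dcfg)
    corrected <- drift_res$localizations
    paths$corrected <- file.path(out_dir, "localizations_corrected.csv")
    paths$drift <- file.path(out_dir, "drift.csv")
    write_localizations(corrected, paths$corrected)
    write_drift_track(drift_res$track, paths$drift)
  }

  img <- NULL
  if (!isFALSE((cfg$render %||% list())$enabled) && nrow(corrected) > 0) {
    rargs <- cfg$render %||% list()
    rargs$enabled <- NULL
    img <- do.call(render, c(list(set = corrected), rargs))
    paths$render <- file.path(out_dir, "render.tif")
    write_render(img, paths$render)
  }

  quant <- list()
  qcfg <- cfg$quantify %||% list()
  if (!is.null(qcfg$line)) {
    prof <- cross_section_profile(corrected, as.numeric(qcfg$line),
                                  band_halfwidth = qcfg$band_halfwidth %||% 300,
                                  bin_width = qcfg$bin_width %||% 10)
    quant$fwhm <- glance(fit_profile_fwhm(prof))
  }
  if (!is.null(qcfg$roi)) {
    roi <- as.matrix(utils::read.csv(qcfg$roi, header = FALSE,
                                     col.names = c("x_nm", "y_nm")))
    quant$density <- localization_density(corrected, roi)
  }
  if (isTRUE(qcfg$blinking)) {
    quant$blinking <- glance(blinking_events(
      corrected, link_radius = qcfg$link_radius %||% 50,
      max_gap = qcfg$max_gap %||% 2))
  }
  if (length(quant)) {
    paths$quantification <- file.path(out_dir, "quantification.csv")
    flat <- dplyr::bind_rows(lapply(names(quant), function(nm) {
      tidyr::pivot_longer(dplyr::mutate(quant[[nm]],
                                        dplyr::across(dplyr::everything(), as.character)),
                          dplyr::everything(), names_to = "key", values_to = "value") |>
        dplyr::mutate(measure = nm, .before = 1)
    }))
    readr::write_csv(flat, paths$quantification, progress = FALSE)
  }

  log <- list(package_version = as.character(utils::packageVersion("smlmr")),
              timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
              config = cfg, artifacts = paths)
  yaml::write_yaml(log, file.path(out_dir, "run_log.yaml"))

  invisible(list(localizations = locs, corrected = corrected, drift = drift_res,
                 image = img, quantification = quant, truth = truth,
                 paths = paths))
}

#' Quick scatter plot of a localization set
#'
#' @param set Localization tibble.
#' @param color Column to map to color (default frame).
#' @return A ggplot object.
#' @export
plot_localizations <- function(set, color = "frame") {
  validate_localizations(set)
  ggplot2::ggplot(set, ggplot2::aes(x = .data$x_nm, y = .data$y_nm,
                                    color = .data[[color]])) +
    ggplot2::geom_point(size = 0.3, alpha = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)")
}
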
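#' Scene specification for the blinking-emitter simulator
#'
#' Defines a synthetic dSTORM acquisition: emitter geometry, blinking
#' statistics, photon budget, stage drift and camera. Defaults emulate the
#' acquisition the pipeline targets: 100 nm pixels, 20 ms exposure at 25
#' frames/s, 15,000-frame sequences, on average 9 blinking events per emitter
#' per sequence, and a photon budget (1,000 photons per on-frame over a
#' background of 10 photons/pixel) that yields roughly 12 nm positional
#' accuracy.
#'
#' Geometries: `"random"` (uniform in the field with a border margin),
#' `"filopodium"` (points along a line segment with Gaussian transverse
#' scatter — a thin filament of defined FWHM), `"ring"` (circle of given
#' radius with Gaussian radial scatter — a peripheral band), `"grid"`
#' (regular bead-like array).
#'
#' @param geometry One of "random", "filopodium", "ring", "grid".
#' @param n_emitters Number of fluorophores.
#' @param width_px,height_px Field size in camera pixels.
#' @param frames Sequence length (frames).
#' @param photon_mean Expected photons per emitter per on-frame.
#' @param background_mean Expected background photons per pixel per frame.
#' @param psf_sigma_nm PSF Gaussian sigma (nm).
#' @param blink_mean_events Mean blinking events per emitter per sequence.
#' @param blink_mean_on Mean on-duration of one event (frames).
#' @param drift_nm Total linear stage drift `c(dx, dy)` in nm accumulated
#'   from the first to the last frame.
#' @param accuracy_nm Localization jitter used by
#'   [simulate_localizations()] (bypasses the image stage).
#' @param camera A [camera_model()].
#' @param line Filopodium endpoints `c(x1, y1, x2, y2)` in nm.
#' @param transverse_sigma_nm Transverse scatter sigma of the filopodium.
#' @param ring_center,ring_radius_nm,ring_sigma_nm Ring geometry (nm).
#' @param grid_margin_px Border margin for random/grid geometry (px).
#' @param seed Integer seed fixing the whole random stream.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(geometry = c("random", "filopodium", "ring", "grid"),
                       n_emitters = 50, width_px = 64, height_px = 64,
                       frames = 15000, photon_mean = 1000,
                       background_mean = 10, psf_sigma_nm = 150,
                       blink_mean_events = 9, blink_mean_on = 3,
                       drift_nm = c(0, 0), accuracy_nm = 12,
                       camera = camera_model(),
                       line = NULL, transverse_sigma_nm = 48.83,
                       ring_center = NULL, ring_radius_nm = 1500,
                       ring_sigma_nm = 100, grid_margin_px = 10,
                       seed = 1L) {
  geometry <- match.arg(geometry)
  if (frames < 1) abort("`frames` must be >= 1.")
  if (n_emitters < 0 || photon_mean < 0 || background_mean < 0 ||
      blink_mean_events < 0 || blink_mean_on <= 0)
    abort("rates must be non-negative (and `blink_mean_on` > 0).")
  structure(as.list(environment()), class = "scene_spec")
}

field_extent_nm <- function(spec) {
  a <- spec$camera$pixel_size_nm
  c(x = spec$width_px * a, y = spec$height_px * a)
}

place_emitters <- function(spec) {
  a <- spec$camera$pixel_size_nm
  ext <- field_extent_nm(spec)
  m <- spec$grid_margin_px * a
  n <- spec$n_emitters
  switch(spec$geometry,
    random = tibble(x_nm = runif(n, m, ext["x"] - m),
                    y_nm = runif(n, m, ext["y"] - m)),
    filopodium = {
      line <- spec$line %||% c(m, ext["y"] / 2, ext["x"] - m, ext["y"] / 2)
      u <- c(line[3] - line[1], line[4] - line[2])
      len <- sqrt(sum(u^2)); u <- u / len
      nv <- c(-u[2], u[1])
      along <- runif(n, 0, len)
      off <- rnorm(n, 0, spec$transverse_sigma_nm)
      tibble(x_nm = line[1] + along * u[1] + off * nv[1],
             y_nm = line[2] + along * u[2] + off * nv[2])
    },
    ring = {
      ctr <- spec$ring_center %||% c(ext["x"] / 2, ext["y"] / 2)
      th <- runif(n, 0, 2 * pi)
      r <- spec$ring_radius_nm + rnorm(n, 0, spec$ring_sigma_nm)
      tibble(x_nm = ctr[1] + r * cos(th), y_nm = ctr[2] + r * sin(th))
    },
    grid = {
      k <- ceiling(sqrt(n))
      gx <- seq(m, ext["x"] - m, length.out = k)
      gy <- seq(m, ext["y"] - m, length.out = k)
      g <- expand.grid(x_nm = gx, y_nm = gy)[seq_len(n), ]
      as_tibble(g)
    })
}

draw_intervals <- function(spec) {
  # events ~ Poisson(mean), starts uniform, on-durations geometric (mean
  # blink_mean_on); overlapping intervals of one emitter merge, so
  # events_per_emitter counts the merged on-intervals actually emitted.
  out <- vector("list", spec$n_emitters)
  for (e in seq_len(spec$n_emitters)) {
    k <- rpois(1, spec$blink_mean_events)
    if (k == 0) { out[[e]] <- NULL; next }
    start <- sort(sample.int(spec$frames, k, replace = TRUE))
    dur <- 1 + rgeom(k, 1 / spec$blink_mean_on)
    last <- pmin(start + dur - 1, spec$frames)
    iv <- data.frame(first_frame = start, last_frame = last)
    merged <- iv[1, ]
    if (k > 1) for (j in 2:k) {
      if (iv$first_frame[j] <= merged$last_frame[nrow(merged)] + 1) {
        merged$last_frame[nrow(merged)] <-
          max(merged$last_frame[nrow(merged)], iv$last_frame[j])
      } else merged <- rbind(merged, iv[j, ])
    }
    merged$emitter <- e
    out[[e]] <- merged
  }
  iv <- dplyr::bind_rows(out)
  if (nrow(iv) == 0) return(tibble(emitter = integer(), first_frame = integer(),
                                   last_frame = integer()))
  as_tibble(iv[c("emitter", "first_frame", "last_frame")])
}

build_truth <- function(spec, emitters, intervals) {
  ev <- dplyr::count(intervals, .data$emitter, name = "events")
  emitters$emitter <- seq_len(nrow(emitters))
  emitters <- dplyr::left_join(emitters, ev, by = "emitter")
  emitters$events[is.na(emitters$events)] <- 0L
  structure(list(emitters = emitters[c("emitter", "x_nm", "y_nm", "events")],
                 intervals = intervals,
                 photons_per_frame = spec$photon_mean,
                 seed = spec$seed),
            class = "smlm_truth")
}

#' @export
print.smlm_truth <- function(x, ...) {
  cat(sprintf("<smlm_truth> %d emitters, %d on-intervals, %.0f photons/frame, seed %d\n",
              nrow(x$emitters), nrow(x$intervals), x$photons_per_frame, x$seed))
  invisible(x)
}

#' Per-frame drift of a scene (nm)
#'
#' Linear ramp from (0, 0) at frame 1 to `drift_nm` at the last frame.
#'
#' @param spec A [scene_spec()].
#' @return Tibble `frame, dx_nm, dy_nm`.
#' @export
scene_drift <- function(spec) {
  f <- seq_len(spec$frames)
  s <- if (spec$frames == 1) rep(0, 1) else (f - 1) / (spec$frames - 1)
  tibble(frame = f, dx_nm = spec$drift_nm[1] * s, dy_nm = spec$drift_nm[2] * s)
}

#' Simulate a localization table directly (no image stage)
#'
#' Emits one record per emitter per on-frame at the true position plus the
#' frame's cumulative drift plus isotropic Gaussian jitter of
#' `spec$accuracy_nm`. Used to exercise drift correction and quantification
#' in isolation from detection/fitting.
#'
#' @param spec A [scene_spec()].
#' @return List with `localizations` (standard columns plus the ground-truth
#'   `emitter` id) and `truth` (an `smlm_truth`).
#' @export
simulate_localizations <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  withr::with_seed(spec$seed, {
    emitters <- place_emitters(spec)
    intervals <- draw_intervals(spec)
    truth <- build_truth(spec, emitters, intervals)
    dr <- scene_drift(spec)
    if (nrow(intervals) == 0) {
      locs <- tibble(frame = integer(), x_nm = double(), y_nm = double(),
                     photons = double(), background_photons = double(),
                     sigma_psf_nm = double(), uncertainty_nm = double(),
                     emitter = integer())
      return(list(localizations = locs, truth = truth))
    }
    rows <- purrr::pmap(intervals, function(emitter, first_frame, last_frame) {
      fr <- first_frame:last_frame
      tibble(frame = fr, emitter = emitter)
    })
    recs <- dplyr::bind_rows(rows)
    recs$x_nm <- truth$emitters$x_nm[recs$emitter] + dr$dx_nm[recs$frame] +
      rnorm(nrow(recs), 0, spec$accuracy_nm)
    recs$y_nm <- truth$emitters$y_nm[recs$emitter] + dr$dy_nm[recs$frame] +
      rnorm(nrow(recs), 0, spec$accuracy_nm)
    recs$photons <- spec$photon_mean
    recs$background_photons <- spec$background_mean
    recs$sigma_psf_nm <- spec$psf_sigma_nm
    recs$uncertainty_nm <- spec$accuracy_nm
    recs <- dplyr::arrange(recs, .data$frame, .data$emitter)
    locs <- recs[c("frame", "x_nm", "y_nm", "photons", "background_photons",
                   "sigma_psf_nm", "uncertainty_nm", "emitter")]
    list(localizations = locs, truth = truth)
  })
}

#' Simulate a raw EMCCD image stack
#'
#' For every frame, each emitter that is "on" contributes an
#' integrated-Gaussian PSF spot ([erf_model()]) at its true position plus the
#' frame's cumulative drift; the photon image (spots + flat background) is
#' Poisson-sampled and converted to camera counts
#' `ADU = offset + gain * photons + read noise`, rounded and clipped to the
#' unsigned 16-bit range. The EMCCD excess-noise factor is not modeled (gain
#' is treated as deterministic).
#'
#' @param spec A [scene_spec()].
#' @return List with `stack` (an [image_stack()], ADU) and `truth`.
#' @export
simulate_stack <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  cam <- spec$camera
  a <- cam$pixel_size_nm
  ext <- field_extent_nm(spec)
  withr::with_seed(spec$seed, {
    emitters <- place_emitters(spec)
    if (any(emitters$x_nm < 0 | emitters$x_nm > ext["x"] |
            emitters$y_nm < 0 | emitters$y_nm > ext["y"]))
      abort("emitters fall outside the field of view.")
    intervals <- draw_intervals(spec)
    truth <- build_truth(spec, emitters, intervals)
    dr <- scene_drift(spec)

    # frame -> emitter lookup
    on_at <- vector("list", spec$frames)
    if (nrow(intervals) > 0) {
      for (j in seq_len(nrow(intervals))) {
        fr <- intervals$first_frame[j]:intervals$last_frame[j]
        for (f in fr) on_at[[f]] <- c(on_at[[f]], intervals$emitter[j])
      }
    }

    nr <- spec$height_px; nc <- spec$width_px
    frames <- vector("list", spec$frames)
    for (f in seq_len(spec$frames)) {
      mu <- matrix(spec$background_mean, nr, nc)
      for (e in on_at[[f]]) {
        mu <- mu + erf_model(nc, nr,
                             emitters$x_nm[e] + dr$dx_nm[f],
                             emitters$y_nm[e] + dr$dy_nm[f],
                             spec$photon_mean, 0, spec$psf_sigma_nm, a)
      }
      photons <- matrix(rpois(nr * nc, mu), nr, nc)
      adu <- cam$offset_adu + cam$em_gain * photons +
        rnorm(nr * nc, 0, cam$read_noise_adu)
      frames[[f]] <- matrix(pmin(pmax(round(adu), 0), 65535), nr, nc)
    }
    stack <- image_stack(frames, pixel_size_nm = a, exposure_ms = 20, units = "adu")
    list(stack = stack, truth = truth)
  })
}

#' Write a ground-truth table as CSV
#'
#' Schema: `emitter,x_nm,y_nm,first_frame,last_frame,photons`.
#'
#' @param truth An `smlm_truth`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  tab <- dplyr::left_join(truth$intervals, truth$emitters, by = "emitter")
  tab$photons <- truth$photons_per_frame
  readr::write_csv(tab[c("emitter", "x_nm", "y_nm", "first_frame",
                         "last_frame", "photons")], path, progress = FALSE)
  invisible(path)
}
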
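#' Drift-correction configuration
#'
#' Parameters of the marker-less drift correction. The Parzen-window kernel
#' width `kernel_sigma` defaults to the median fitted positional accuracy of
#' the input set; the per-step shift cap ("max-limit-drift") is
#' `max_drift_factor` times that median accuracy; track smoothing uses a
#' cubic smoothing spline, either inside sliding time windows (parameter
#' `smoothing_p_window`, default 1e-4) or over the entire timeline
#' (`smoothing_p_global`, default 1e-6).
#'
#' @param group_mode "frames" (equal time intervals) or "points" (equal
#'   number of localizations per group).
#' @param group_size Frames per group ("frames" mode) or localizations per
#'   group ("points" mode).
#' @param kernel_sigma Parzen kernel sigma in nm; `NULL` = median accuracy.
#' @param max_drift_factor Cap factor c: max-limit-drift = c * median accuracy.
#' @param smoothing_mode "global" or "windowed".
#' @param smoothing_p_window Spline parameter for windowed smoothing.
#' @param smoothing_p_global Spline parameter for global smoothing.
#' @param window_frames Sliding-window length in frames (windowed mode).
#' @return A `drift_config` list.
#' @export
drift_config <- function(group_mode = c("frames", "points"), group_size = 500,
                         kernel_sigma = NULL, max_drift_factor = 3,
                         smoothing_mode = c("global", "windowed"),
                         smoothing_p_window = 1e-4, smoothing_p_global = 1e-6,
                         window_frames = 1000) {
  group_mode <- match.arg(group_mode)
  smoothing_mode <- match.arg(smoothing_mode)
  if (group_size < 1) abort("`group_size` must be >= 1.")
  if (!is.null(kernel_sigma) && kernel_sigma <= 0) abort("`kernel_sigma` must be > 0.")
  for (p in c(smoothing_p_window, smoothing_p_global))
    if (p <= 0 || p >= 1) abort("smoothing parameters must lie in (0, 1).")
  structure(list(group_mode = group_mode, group_size = group_size,
                 kernel_sigma = kernel_sigma, max_drift_factor = max_drift_factor,
                 smoothing_mode = smoothing_mode,
                 smoothing_p_window = smoothing_p_window,
                 smoothing_p_global = smoothing_p_global,
                 window_frames = window_frames),
            class = "drift_config")
}

#' Partition a localization set into drift groups
#'
#' "frames" mode cuts the sequence into consecutive blocks of `group_size`
#' frames (last block may be short); "points" mode cuts the frame-ordered
#' record list into consecutive blocks of `group_size` localizations, which
#' makes the group time spans variable but the point counts equal.
#'
#' @param set Localization tibble.
#' @param config A [drift_config()].
#' @return `set` ordered by frame with an integer `group` column.
#' @export
group_localizations <- function(set, config = drift_config()) {
  validate_localizations(set)
  if (nrow(set) == 0) abort("empty localization set.")
  set <- dplyr::arrange(set, .data$frame)
  if (config$group_mode == "frames") {
    set$group <- as.integer((set$frame - 1) %/% config$group_size + 1)
    set$group <- as.integer(factor(set$group, levels = sort(unique(set$group))))
  } else {
    set$group <- as.integer((seq_len(nrow(set)) - 1) %/% config$group_size + 1)
  }
  if (max(set$group) == 1)
    warn("a single group: drift correction degenerates to the identity.")
  set
}

#' Parzen-window registration cost function
#'
#' Similarity of a shifted moving point set to a fixed basis set:
#' \deqn{CF(d) = \sum_j \sum_i \frac{1}{2\pi\sigma^2}
#'   \exp\!\left(-\frac{\|p_j + d - p_i\|^2}{2\sigma^2}\right)}
#' summed over all moving x fixed pairs. Drift estimation maximizes CF over
#' the translation d.
#'
#' @param moving Two-column matrix (x, y in nm) of the movable set.
#' @param fixed Two-column matrix of the basis set.
#' @param d Shift vector `c(alpha, beta)` in nm applied to `moving`.
#' @param sigma Kernel sigma in nm, > 0.
#' @return The scalar CF value; 0 (with a warning) when either set is empty.
#' @export
cost_function <- function(moving, fixed, d = c(0, 0), sigma) {
  if (sigma <= 0) abort("`sigma` must be > 0.")
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (nrow(moving) == 0 || nrow(fixed) == 0) {
    warn("empty point set in cost_function; returning 0.")
    return(0)
  }
  norm_const <- 1 / (2 * pi * sigma^2)
  total <- 0
  mx <- moving[, 1] + d[1]; my <- moving[, 2] + d[2]
  fx <- fixed[, 1]; fy <- fixed[, 2]
  # chunk the moving set to bound the pairwise matrix at ~1e6 entries
  chunk <- max(1L, floor(1e6 / nrow(fixed)))
  for (i0 in seq(1L, nrow(moving), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nrow(moving))
    d2 <- outer(mx[i0:i1], fx, "-")^2 + outer(my[i0:i1], fy, "-")^2
    total <- total + sum(exp(-d2 / (2 * sigma^2)))
  }
  norm_const * total
}

#' Estimate the drift shift of one group against the basis set
#'
#' Maximizes the Parzen-window cost over translations with quasi-Newton
#' (BFGS) ascent, started from the best node of a coarse grid (span
#' `init` +/- 3 sigma, step sigma/2) to escape local maxima of the
#' multi-modal cost surface. The result is capped so that
#' `||d - init|| <= max_drift` ("max-limit-drift"); with the default
#' `init = c(0, 0)` this caps the absolute shift.
#'
#' @param moving Two-column position matrix of the group being registered.
#' @param basis Two-column position matrix of the accumulated basis set.
#' @param sigma Kernel sigma (nm).
#' @param max_drift Cap on the shift length relative to `init` (nm);
#'   `Inf` disables the cap.
#' @param init Warm-start shift (nm), typically the previous group's shift.
#' @return List `d` (length-2 shift), `cf_value`, `capped`.
#' @export
estimate_group_shift <- function(moving, basis, sigma, max_drift = Inf,
                                 init = c(0, 0)) {
  moving <- as.matrix(moving); basis <- as.matrix(basis)
  if (nrow(moving) == 0 || nrow(basis) == 0) abort("both point sets must be non-empty.")
  grid1 <- seq(-3 * sigma, 3 * sigma, by = sigma / 2)
  grid <- as.matrix(expand.grid(a = init[1] + grid1, b = init[2] + grid1))
  cf_grid <- apply(grid, 1, function(g) cost_function(moving, basis, g, sigma))
  best <- which.max(cf_grid)
  opt <- optim(grid[best, ],
               fn = function(g) -cost_function(moving, basis, g, sigma),
               method = "BFGS", control = list(maxit = 200, reltol = 1e-10))
  d <- opt$par
  # guard against an ascent failure: never fall below the best grid node
  if (-opt$value < cf_grid[best]) d <- grid[best, ]
  capped <- FALSE
  len <- sqrt(sum((d - init)^2))
  if (is.finite(max_drift) && len > max_drift) {
    d <- init + (d - init) * (max_drift / len)
    capped <- TRUE
  }
  list(d = unname(d),
       cf_value = cost_function(moving, basis, d, sigma),
       capped = capped)
}

#' Smooth a raw drift track and evaluate it at every frame
#'
#' Fits the p-parameterized cubic smoothing spline ([smoothing_spline()]) to
#' the raw per-group shifts, separately in x and y, and evaluates it at every
#' frame 1..n_frames. Global mode fits one spline over the whole timeline
#' (p = 1e-6 by default); windowed mode fits inside sliding windows of
#' `window_frames` frames advancing by half a window (p = 1e-4 by default)
#' and averages the overlapping estimates.
#'
#' @param raw Tibble with columns `frame, alpha_nm, beta_nm` (raw shifts at
#'   group mid-frames).
#' @param n_frames Number of frames the track must cover.
#' @param config A [drift_config()].
#' @return Tibble `frame, alpha_nm, beta_nm` with one row per frame.
#' @export
smooth_track <- function(raw, n_frames, config = drift_config()) {
  frames <- seq_len(n_frames)
  if (nrow(raw) < 2) {
    val <- if (nrow(raw) == 1) c(raw$alpha_nm, raw$beta_nm) else c(0, 0)
    return(tibble(frame = frames, alpha_nm = rep(val[1], n_frames),
                  beta_nm = rep(val[2], n_frames)))
  }
  fit_one <- function(y) {
    if (config$smoothing_mode == "global") {
      return(smoothing_spline(raw$frame, y, config$smoothing_p_global, frames))
    }
    w <- config$window_frames
    last_start <- max(n_frames - w + 1, 1)
    starts <- unique(c(seq(1, last_start, by = max(1, w %/% 2)), last_start))
    acc <- numeric(n_frames); cnt <- numeric(n_frames)
    for (s in starts) {
      lo <- s; hi <- min(s + w - 1, n_frames)
      in_win <- raw$frame >= lo & raw$frame <= hi
      if (sum(in_win) < 2) next
      est <- smoothing_spline(raw$frame[in_win], y[in_win],
                              config$smoothing_p_window, lo:hi)
      acc[lo:hi] <- acc[lo:hi] + est
      cnt[lo:hi] <- cnt[lo:hi] + 1
    }
    if (any(cnt == 0)) {       # frames no window could cover: fall back linearly
      covered <- which(cnt > 0)
      if (length(covered) == 0)
        return(approx(raw$frame, y, xout = frames, rule = 2)$y)
      acc[covered] <- acc[covered] / cnt[covered]
      return(approx(covered, acc[covered], xout = frames, rule = 2)$y)
    }
    acc / cnt
  }
  tibble(frame = frames, alpha_nm = fit_one(raw$alpha_nm),
         beta_nm = fit_one(raw$beta_nm))
}

#' Marker-less drift correction of a localization set
#'
#' Sequential Parzen-window registration: the first group initializes the
#' basis set; each subsequent group is registered against the accumulated
#' basis by maximizing the cost function over translations, shifted, and
#' merged into the basis. The raw per-group shifts (anchored at group
#' mid-frames) are then smoothed into a continuous per-frame track that is
#' applied to every localization.
#'
#' @param set Localization tibble (needs `uncertainty_nm` unless
#'   `config$kernel_sigma` is given).
#' @param config A [drift_config()].
#' @return An object of class `smlm_drift` with elements
#'   `localizations` (corrected set, same rows/columns as the input),
#'   `track` (per-frame `frame, alpha_nm, beta_nm`),
#'   `shifts` (raw per-group shifts with CF values and cap flags), and
#'   `config`. `tidy()` returns the track, `glance()` a one-row summary.
#' @export
correct_drift <- function(set, config = drift_config()) {
  validate_localizations(set)
  if (nrow(set) == 0) abort("empty localization set.")
  sigma <- config$kernel_sigma
  med_acc <- if ("uncertainty_nm" %in% names(set)) median(set$uncertainty_nm) else NA_real_
  if (is.null(sigma)) {
    if (!is.finite(med_acc))
      abort("no `uncertainty_nm` column: supply `kernel_sigma` explicitly.")
    sigma <- med_acc
  }
  max_drift <- config$max_drift_factor * (if (is.finite(med_acc)) med_acc else sigma)

  grouped <- group_localizations(set, config)
  n_fr <- max(grouped$frame)
  groups <- split(seq_len(nrow(grouped)), grouped$group)
  K <- length(groups)

  pos <- cbind(grouped$x_nm, grouped$y_nm)
  shifts <- matrix(0, K, 2)
  cf_vals <- rep(NA_real_, K)
  capped <- rep(FALSE, K)
  mid_frames <- vapply(groups, function(idx)
    floor((min(grouped$frame[idx]) + max(grouped$frame[idx])) / 2), 0)

  if (K > 1) {
    basis <- pos[groups[[1]], , drop = FALSE]
    d_prev <- c(0, 0)
    for (i in 2:K) {
      idx <- groups[[i]]
      moving <- pos[idx, , drop = FALSE]
      if (nrow(moving) < 3) {
        warn(sprintf("group %d has < 3 points; carrying the previous shift forward.", i))
        d <- d_prev
        cf_vals[i] <- NA_real_
      } else {
        est <- estimate_group_shift(moving, basis, sigma = sigma,
                                    max_drift = max_drift, init = d_prev)
        d <- est$d
        cf_vals[i] <- est$cf_value
        capped[i] <- est$capped
      }
      shifts[i, ] <- d
      basis <- rbind(basis, sweep(moving, 2, -d))
      d_prev <- d
    }
  }

  raw <- tibble(frame = as.integer(mid_frames),
                alpha_nm = shifts[, 1], beta_nm = shifts[, 2])
  track <- smooth_track(raw, n_fr, config)

  corrected <- set
  ai <- track$alpha_nm[corrected$frame]
  bi <- track$beta_nm[corrected$frame]
  corrected$x_nm <- corrected$x_nm + ai
  corrected$y_nm <- corrected$y_nm + bi

  structure(
    list(localizations = corrected,
         track = track,
         shifts = dplyr::mutate(raw, group = dplyr::row_number(),
                                cf_value = cf_vals, capped = capped),
         kernel_sigma = sigma, max_drift = max_drift, config = config),
    class = "smlm_drift"
  )
}

#' @export
print.smlm_drift <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<smlm_drift> %d localizations, %d groups, kernel sigma %.2f nm\n  track span x [%.1f, %.1f] nm, y [%.1f, %.1f] nm, %d capped step(s)\n",
    nrow(x$localizations), nrow(x$shifts), x$kernel_sigma,
    min(x$track$alpha_nm), max(x$track$alpha_nm),
    min(x$track$beta_nm), max(x$track$beta_nm), g$n_capped))
  invisible(x)
}

#' @method tidy smlm_drift
#' @export
tidy.smlm_drift <- function(x, ...) x$track

#' @method glance smlm_drift
#' @export
glance.smlm_drift <- function(x, ...) {
  tibble(n_localizations = nrow(x$localizations),
         n_groups = nrow(x$shifts),
         n_capped = sum(x$shifts$capped, na.rm = TRUE),
         kernel_sigma_nm = x$kernel_sigma,
         max_drift_nm = x$max_drift,
         track_rms_nm = sqrt(mean(x$track$alpha_nm^2 + x$track$beta_nm^2)))
}

#' @method autoplot smlm_drift
#' @export
autoplot.smlm_drift <- function(object, ...) {
  tr <- tidyr::pivot_longer(object$track, c("alpha_nm", "beta_nm"),
                            names_to = "axis", values_to = "shift_nm")
  rw <- tidyr::pivot_longer(object$shifts, c("alpha_nm", "beta_nm"),
                            names_to = "axis", values_to = "shift_nm")
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$frame, y = .data$shift_nm)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(data = rw, size = 1, alpha = 0.7) +
    ggplot2::facet_wrap(~axis, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "frame", y = "drift compensation (nm)",
                  title = "Estimated drift track (points: raw group shifts)")
}
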
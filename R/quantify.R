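#' Cross-section profile of a structure
#'
#' Projects localizations (or rendered-image pixels) onto the normal of a
#' line segment drawn along the structure axis and histograms the signed
#' perpendicular offsets. Only records within `band_halfwidth` of the line
#' and whose along-axis projection falls inside the segment contribute.
#'
#' @param x Localization tibble or an `smlm_image`.
#' @param line Numeric `c(x1, y1, x2, y2)` in nm: the structure axis.
#' @param band_halfwidth Half width of the sampling band (nm).
#' @param bin_width Histogram bin width (nm).
#' @param min_records Minimum number of contributing localizations.
#' @param ... Passed to methods.
#' @return A tibble `offset_nm` (bin centers), `value` (count or summed
#'   intensity), class `smlm_profile`.
#' @export
cross_section_profile <- function(x, line, band_halfwidth = 300,
                                  bin_width = 10, ...) {
  UseMethod("cross_section_profile")
}

profile_geometry <- function(line) {
  p1 <- line[1:2]; p2 <- line[3:4]
  u <- p2 - p1
  len <- sqrt(sum(u^2))
  if (len == 0) abort("zero-length profile line.")
  u <- u / len
  list(p1 = p1, u = u, n = c(-u[2], u[1]), len = len)
}

bin_offsets <- function(off, w, band_halfwidth, bin_width) {
  breaks <- seq(-band_halfwidth, band_halfwidth, by = bin_width)
  if (tail(breaks, 1) < band_halfwidth) breaks <- c(breaks, band_halfwidth)
  idx <- findInterval(off, breaks, rightmost.closed = TRUE)
  ok <- idx >= 1 & idx <= length(breaks) - 1
  val <- tapply(w[ok], factor(idx[ok], levels = seq_len(length(breaks) - 1)), sum)
  val[is.na(val)] <- 0
  centers <- (head(breaks, -1) + tail(breaks, -1)) / 2
  structure(tibble(offset_nm = centers, value = as.numeric(val)),
            class = c("smlm_profile", "tbl_df", "tbl", "data.frame"))
}

#' @rdname cross_section_profile
#' @export
cross_section_profile.data.frame <- function(x, line, band_halfwidth = 300,
                                             bin_width = 10, min_records = 10,
                                             ...) {
  validate_localizations(x)
  if (band_halfwidth <= 0 || bin_width <= 0)
    abort("`band_halfwidth` and `bin_width` must be > 0.")
  g <- profile_geometry(line)
  vx <- x$x_nm - g$p1[1]; vy <- x$y_nm - g$p1[2]
  along <- vx * g$u[1] + vy * g$u[2]
  off <- vx * g$n[1] + vy * g$n[2]
  keep <- along >= 0 & along <= g$len & abs(off) <= band_halfwidth
  if (sum(keep) < min_records)
    abort(sprintf("only %d localizations in the band (need >= %d).",
                  sum(keep), min_records))
  bin_offsets(off[keep], rep(1, sum(keep)), band_halfwidth, bin_width)
}

#' @rdname cross_section_profile
#' @export
cross_section_profile.smlm_image <- function(x, line, band_halfwidth = 300,
                                             bin_width = 10, ...) {
  px <- attr(x, "pixel_size_nm"); org <- attr(x, "origin_nm")
  g <- profile_geometry(line)
  idx <- arrayInd(seq_along(x), dim(x))  # every pixel (row, col)
  cx <- org[1] + (idx[, 2] - 0.5) * px
  cy <- org[2] + (idx[, 1] - 0.5) * px
  vx <- cx - g$p1[1]; vy <- cy - g$p1[2]
  along <- vx * g$u[1] + vy * g$u[2]
  off <- vx * g$n[1] + vy * g$n[2]
  w <- unclass(x)[idx]
  keep <- along >= 0 & along <= g$len & abs(off) <= band_halfwidth
  bin_offsets(off[keep], w[keep], band_halfwidth, bin_width)
}

#' Gaussian fit of a cross-section profile
#'
#' Least-squares fit of `offset + amplitude * exp(-(x - center)^2 / (2 sigma^2))`
#' to a profile histogram; the full width at half maximum is
#' `2 * sqrt(2 * log(2)) * sigma` (= 2.3548 sigma).
#'
#' @param profile Tibble with `offset_nm` and `value` (from
#'   [cross_section_profile()]).
#' @return An `smlm_profile_fit` with `amplitude`, `center_nm`, `sigma_nm`,
#'   `offset`, `fwhm_nm`, `converged`, and the data. Supports `tidy()`,
#'   `glance()` and `autoplot()`.
#' @export
fit_profile_fwhm <- function(profile) {
  if (!all(c("offset_nm", "value") %in% names(profile)))
    abort("`profile` needs columns `offset_nm` and `value`.")
  x <- profile$offset_nm; y <- profile$value
  if (length(x) < 5) abort("need at least 5 bins.")
  if (sd(y) == 0) abort("flat profile: nothing to fit.")
  off0 <- min(y)
  amp0 <- max(y) - off0
  wt <- pmax(y - off0, 0)
  c0 <- if (sum(wt) > 0) weighted.mean(x, wt) else mean(x)
  s0 <- if (sum(wt) > 0) sqrt(weighted.mean((x - c0)^2, wt)) else diff(range(x)) / 4
  s0 <- max(s0, diff(range(x)) / 100)
  fit <- minpack.lm::nls.lm(
    par = c(amp = amp0, center = c0, sigma = s0, offset = off0),
    lower = c(0, min(x), 1e-6, -Inf), upper = c(Inf, max(x), diff(range(x)), Inf),
    fn = function(p) y - (p[4] + p[1] * exp(-(x - p[2])^2 / (2 * p[3]^2))),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- fit$par
  res <- structure(
    list(amplitude = p[[1]], center_nm = p[[2]], sigma_nm = p[[3]],
         offset = p[[4]], fwhm_nm = 2 * sqrt(2 * log(2)) * p[[3]],
         converged = fit$info %in% 1:4, residual_norm = sqrt(sum(fit$fvec^2)),
         profile = tibble(offset_nm = x, value = y)),
    class = "smlm_profile_fit")
  if (!res$converged) warn("profile fit did not converge.")
  res
}

#' @export
print.smlm_profile_fit <- function(x, ...) {
  cat(sprintf("<smlm_profile_fit> FWHM %.1f nm (sigma %.1f nm), center %.1f nm%s\n",
              x$fwhm_nm, x$sigma_nm, x$center_nm,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' @method tidy smlm_profile_fit
#' @export
tidy.smlm_profile_fit <- function(x, ...) {
  tibble(term = c("amplitude", "center_nm", "sigma_nm", "offset"),
         estimate = c(x$amplitude, x$center_nm, x$sigma_nm, x$offset))
}

#' @method glance smlm_profile_fit
#' @export
glance.smlm_profile_fit <- function(x, ...) {
  tibble(fwhm_nm = x$fwhm_nm, sigma_nm = x$sigma_nm, center_nm = x$center_nm,
         converged = x$converged, residual_norm = x$residual_norm)
}

#' @method augment smlm_profile_fit
#' @export
augment.smlm_profile_fit <- function(x, ...) {
  dplyr::mutate(x$profile,
                .fitted = x$offset + x$amplitude *
                  exp(-(.data$offset_nm - x$center_nm)^2 / (2 * x$sigma_nm^2)),
                .resid = .data$value - .data$.fitted)
}

#' @method autoplot smlm_profile_fit
#' @export
autoplot.smlm_profile_fit <- function(object, ...) {
  aug <- augment(object)
  ggplot2::ggplot(aug, ggplot2::aes(x = .data$offset_nm)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$value), fill = "grey70", width = NULL) +
    ggplot2::geom_line(ggplot2::aes(y = .data$.fitted), color = "firebrick") +
    ggplot2::labs(x = "perpendicular offset (nm)", y = "localizations",
                  title = sprintf("Cross-section fit: FWHM = %.0f nm", object$fwhm_nm))
}

#' Localization density inside a region of interest
#'
#' Counts the localizations strictly inside a simple polygon and divides by
#' its shoelace area, reported per square micrometer.
#'
#' @param set Localization tibble.
#' @param roi Two-column matrix/data frame of polygon vertices (x_nm, y_nm),
#'   in order, not self-intersecting.
#' @return A one-row tibble `n_inside, area_um2, density_per_um2`.
#' @export
localization_density <- function(set, roi) {
  validate_localizations(set)
  roi <- as.matrix(roi)
  if (nrow(roi) < 3) abort("`roi` must have at least 3 vertices.")
  area_nm2 <- abs(pracma::polyarea(roi[, 1], roi[, 2]))
  if (area_nm2 <= 0) abort("degenerate polygon: zero area.")
  inside <- if (nrow(set) == 0) logical(0) else
    pracma::inpolygon(set$x_nm, set$y_nm, roi[, 1], roi[, 2], boundary = FALSE)
  area_um2 <- area_nm2 / 1e6
  tibble(n_inside = sum(inside), area_um2 = area_um2,
         density_per_um2 = sum(inside) / area_um2)
}

#' Blinking-event statistics
#'
#' Clusters localizations into putative molecules by single-linkage within
#' `link_radius`, then merges each molecule's consecutive-frame runs
#' separated by gaps of at most `max_gap` off-frames into blinking events.
#'
#' @param set Localization tibble.
#' @param link_radius Spatial linking radius (nm), > 0.
#' @param max_gap Largest tolerated off-gap (frames) inside one event, >= 0.
#' @return An `smlm_blinking` object: `per_molecule` tibble (`molecule`,
#'   `n_records`, `n_events`, `x_nm`, `y_nm`), plus mean/SD/SEM of events per
#'   molecule. `tidy()` returns the per-molecule table, `glance()` the summary.
#' @export
blinking_events <- function(set, link_radius = 50, max_gap = 2) {
  validate_localizations(set)
  if (nrow(set) == 0) abort("empty localization set.")
  if (link_radius <= 0) abort("`link_radius` must be > 0.")
  if (max_gap < 0) abort("`max_gap` must be >= 0.")
  if (nrow(set) == 1) {
    mol <- 1L
  } else {
    hc <- hclust(dist(cbind(set$x_nm, set$y_nm)), method = "single")
    mol <- cutree(hc, h = link_radius)
  }
  per <- dplyr::group_by(dplyr::mutate(set, molecule = mol), .data$molecule)
  per <- dplyr::summarise(
    per,
    n_records = dplyr::n(),
    n_events = {
      fr <- sort(unique(.data$frame))
      if (length(fr) <= 1) 1L else 1L + sum(diff(fr) > max_gap + 1L)
    },
    x_nm = mean(.data$x_nm), y_nm = mean(.data$y_nm), .groups = "drop")
  structure(
    list(per_molecule = per,
         mean_events = mean(per$n_events),
         sd_events = sd(per$n_events),
         sem_events = sd(per$n_events) / sqrt(nrow(per)),
         link_radius = link_radius, max_gap = max_gap),
    class = "smlm_blinking")
}

#' @export
print.smlm_blinking <- function(x, ...) {
  cat(sprintf("<smlm_blinking> %d molecules: %.1f +/- %.1f events (SD; SEM %.2f)\n",
              nrow(x$per_molecule), x$mean_events, x$sd_events, x$sem_events))
  invisible(x)
}

#' @method tidy smlm_blinking
#' @export
tidy.smlm_blinking <- function(x, ...) x$per_molecule

#' @method glance smlm_blinking
#' @export
glance.smlm_blinking <- function(x, ...) {
  tibble(n_molecules = nrow(x$per_molecule), mean_events = x$mean_events,
         sd_events = x$sd_events, sem_events = x$sem_events,
         link_radius_nm = x$link_radius, max_gap = x$max_gap)
}
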
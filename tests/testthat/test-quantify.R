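# One short on-event per emitter so every record is an independent transverse
# draw: the filament width statistic then really has ~n_emitters samples.
sim_filo <- function(n_emitters = 2400, sigma = 50, accuracy = 0.001, seed = 50,
                     frames = 2000) {
  scene_spec(geometry = "filopodium", n_emitters = n_emitters, frames = frames,
             line = c(1000, 3000, 5000, 3500), transverse_sigma_nm = sigma,
             accuracy_nm = accuracy, blink_mean_events = 1, blink_mean_on = 1,
             seed = seed)
}

test_that("records exactly on the line land in the central bin; endpoint swap mirrors", {
  set <- tibble::tibble(frame = 1:20,
                        x_nm = seq(100, 900, length.out = 20), y_nm = 500,
                        photons = 1, background_photons = 0,
                        sigma_psf_nm = 150, uncertainty_nm = 10)
  prof <- cross_section_profile(set, c(0, 500, 1000, 500), band_halfwidth = 100,
                                bin_width = 10)
  expect_equal(sum(prof$value), 20)
  expect_equal(sum(prof$value[abs(prof$offset_nm) < 10]), 20)  # all in the central bins
  # mirror symmetry under endpoint swap (offsets strictly off the bin edges)
  set2 <- dplyr::mutate(set, y_nm = 500 + rep(c(-23, 41), 10))
  a <- cross_section_profile(set2, c(0, 500, 1000, 500), band_halfwidth = 100,
                             bin_width = 10)
  b <- cross_section_profile(set2, c(1000, 500, 0, 500), band_halfwidth = 100,
                             bin_width = 10)
  expect_equal(b$value, rev(a$value))
  expect_error(cross_section_profile(set, c(1, 1, 1, 1)), "zero-length")
  expect_error(cross_section_profile(set[1:3, ], c(0, 500, 1000, 500)), "need >=")
})

test_that("transverse-Gaussian scatter is recovered by the profile histogram", {
  spec <- sim_filo(sigma = 50, seed = 51)
  sim <- simulate_localizations(spec)
  set <- sim$localizations
  expect_gt(nrow(set), 2000)
  g <- c(1000, 3000, 5000, 3500)
  u <- c(4000, 500) / sqrt(4000^2 + 500^2)
  nv <- c(-u[2], u[1])
  off <- (set$x_nm - 1000) * nv[1] + (set$y_nm - 3000) * nv[2]
  expect_lt(abs(sd(off) - 50) / 50, 0.05)    # direct sample statistic
  prof <- cross_section_profile(set, g, band_halfwidth = 300, bin_width = 10)
  # histogram sigma from the binned profile tracks the direct sd
  mu <- weighted.mean(prof$offset_nm, prof$value)
  s_hist <- sqrt(weighted.mean((prof$offset_nm - mu)^2, prof$value))
  expect_lt(abs(s_hist - sd(off)) / sd(off), 0.05)
})

test_that("Gaussian profile fits convert sigma to FWHM exactly", {
  x <- seq(-300, 300, by = 10)
  mk <- function(s) tibble::tibble(offset_nm = x,
                                   value = 80 * exp(-x^2 / (2 * s^2)) + 3)
  f50 <- fit_profile_fwhm(mk(50))
  expect_equal(f50$fwhm_nm, 2 * sqrt(2 * log(2)) * 50, tolerance = 1e-6)
  expect_equal(f50$fwhm_nm / f50$sigma_nm, 2 * sqrt(2 * log(2)), tolerance = 1e-12)
  expect_equal(f50$fwhm_nm, 117.74, tolerance = 1e-4)
  # the diffraction-limited width scale: sigma 286.7 nm -> FWHM 675.1 nm
  x2 <- seq(-900, 900, by = 30)
  f287 <- fit_profile_fwhm(tibble::tibble(
    offset_nm = x2, value = 40 * exp(-x2^2 / (2 * 286.7^2)) + 1))
  expect_equal(f287$fwhm_nm, 675.1, tolerance = 0.1)
  expect_error(fit_profile_fwhm(tibble::tibble(offset_nm = x, value = 5)), "flat")
})

test_that("fitted filopodium FWHM equals the accuracy-broadened truth", {
  spec <- sim_filo(sigma = 115 / (2 * sqrt(2 * log(2))), accuracy = 12,
                   seed = 52)
  sim <- simulate_localizations(spec)
  expect_gt(nrow(sim$localizations), 2000)
  prof <- cross_section_profile(sim$localizations, c(1000, 3000, 5000, 3500),
                                band_halfwidth = 300, bin_width = 10)
  fit <- fit_profile_fwhm(prof)
  broadened <- sqrt(115^2 + (2 * sqrt(2 * log(2)) * 12)^2)  # quadrature convolution
  expect_lt(abs(fit$fwhm_nm - broadened) / broadened, 0.05)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_equal(nrow(tidy(fit)), 4)
})

test_that("density counts strictly inside the polygon per square micrometer", {
  sq <- cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000))
  set.seed(53)
  set <- tibble::tibble(frame = 1L, x_nm = runif(740, 1, 999),
                        y_nm = runif(740, 1, 999), photons = 1,
                        background_photons = 0, sigma_psf_nm = 150,
                        uncertainty_nm = 10)
  d <- localization_density(set, sq)
  expect_equal(d$n_inside, 740)
  expect_equal(d$area_um2, 1)
  expect_equal(d$density_per_um2, 740)
  # empty ROI
  far <- cbind(c(5000, 6000, 6000, 5000), c(5000, 5000, 6000, 6000))
  expect_equal(localization_density(set, far)$density_per_um2, 0)
  expect_error(localization_density(set, cbind(c(0, 1, 2), c(0, 1, 2))), "zero area")
})

test_that("density is invariant under rigid motion and matches a Poisson rate", {
  tri <- cbind(c(0, 3000, 1000), c(0, 0, 2500))
  area_um2 <- abs(pracma::polyarea(tri[, 1], tri[, 2])) / 1e6
  # Monte-Carlo rejection check of the shoelace area
  set.seed(54)
  bx <- runif(200000, 0, 3000); by <- runif(200000, 0, 2500)
  inside <- pracma::inpolygon(bx, by, tri[, 1], tri[, 2])
  mc_area <- mean(inside) * (3000 * 2500) / 1e6
  expect_lt(abs(mc_area - area_um2) / area_um2, 0.02)

  lambda <- 300  # per um^2
  n <- rpois(1, lambda * (3000 * 2500) / 1e6)
  px <- runif(n, 0, 3000); py <- runif(n, 0, 2500)
  keep <- pracma::inpolygon(px, py, tri[, 1], tri[, 2])
  set <- tibble::tibble(frame = 1L, x_nm = px, y_nm = py, photons = 1,
                        background_photons = 0, sigma_psf_nm = 150,
                        uncertainty_nm = 10)
  d <- localization_density(set, tri)
  se <- sqrt(lambda / area_um2)
  expect_lt(abs(d$density_per_um2 - lambda), 3 * se)

  # rotate set and ROI together by 30 degrees and translate
  th <- pi / 6; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  xy <- cbind(set$x_nm, set$y_nm) %*% t(R)
  set2 <- dplyr::mutate(set, x_nm = xy[, 1] + 500, y_nm = xy[, 2] - 200)
  tri2 <- sweep(tri %*% t(R), 2, -c(500, -200))
  d2 <- localization_density(set2, tri2)
  expect_equal(d2$n_inside, d$n_inside)
  expect_equal(d2$density_per_um2, d$density_per_um2, tolerance = 1e-9)
})

test_that("blinking events split on gaps and sum to the record count", {
  mk <- function(frames) tibble::tibble(frame = frames, x_nm = 100, y_nm = 100,
                                        photons = 1, background_photons = 0,
                                        sigma_psf_nm = 150, uncertainty_nm = 5)
  one <- blinking_events(mk(c(1, 2, 3)), link_radius = 50, max_gap = 1)
  expect_equal(one$per_molecule$n_events, 1L)
  two <- blinking_events(mk(c(1, 2, 3, 100, 101, 102)), link_radius = 50, max_gap = 1)
  expect_equal(two$per_molecule$n_events, 2L)
  # a gap of exactly max_gap off-frames merges
  merged <- blinking_events(mk(c(1, 4)), link_radius = 50, max_gap = 2)
  expect_equal(merged$per_molecule$n_events, 1L)
  split <- blinking_events(mk(c(1, 5)), link_radius = 50, max_gap = 2)
  expect_equal(split$per_molecule$n_events, 2L)
  expect_equal(sum(two$per_molecule$n_records), 6)
})

test_that("ground-truth event counts are recovered on well-separated emitters", {
  spec <- scene_spec(geometry = "grid", n_emitters = 25, width_px = 64,
                     height_px = 64, frames = 3000, blink_mean_events = 5,
                     blink_mean_on = 3, accuracy_nm = 10, grid_margin_px = 8,
                     seed = 55)
  sim <- simulate_localizations(spec)
  bl <- blinking_events(sim$localizations, link_radius = 50, max_gap = 0)
  truth <- sim$truth$emitters[sim$truth$emitters$events > 0, ]
  expect_equal(nrow(bl$per_molecule), nrow(truth))
  # match molecules to emitters by position
  got <- bl$per_molecule[order(round(bl$per_molecule$x_nm, -2),
                               round(bl$per_molecule$y_nm, -2)), ]
  want <- truth[order(round(truth$x_nm, -2), round(truth$y_nm, -2)), ]
  expect_equal(got$n_events, want$events)
  expect_s3_class(glance(bl), "tbl_df")
})
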
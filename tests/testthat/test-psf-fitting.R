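cam100 <- camera_model(pixel_size_nm = 100, em_gain = 50, offset_adu = 100)

test_that("erf model: no signal, symmetry, and the exact center-pixel value", {
  # N = 0: background only
  expect_equal(erf_model(9, 9, 450, 450, 0, 7, 150, 100),
               matrix(7, 9, 9))
  # a = s, position at the center-pixel center: [erf(0.5/sqrt(2))]^2
  m <- erf_model(9, 9, 4.5 * 100, 4.5 * 100, 1, 0, 100, 100)
  expect_equal(m[5, 5], (2 * pnorm(0.5) - 1)^2, tolerance = 1e-12)
  # mirroring x0 about the window center mirrors the grid
  left <- erf_model(9, 9, 4.5 * 100 - 130, 450, 1000, 2, 150, 100)
  right <- erf_model(9, 9, 4.5 * 100 + 130, 450, 1000, 2, 150, 100)
  expect_equal(left, right[, 9:1], tolerance = 1e-12)
  expect_error(erf_model(9, 9, 450, 450, 1, 0, s = 0, a = 100), "`s`")
})

test_that("erf model matches 2-D numerical integration of the Gaussian", {
  a <- 100; s <- 150; x0 <- 430; y0 <- 520
  m <- erf_model(5, 5, x0, y0, 1, 0, s, a)
  for (k in 0:4) for (l in 0:4) {
    q <- gauss_pixel_integral(k * a, (k + 1) * a, l * a, (l + 1) * a, x0, y0, s)
    expect_equal(m[l + 1, k + 1], q, tolerance = 1e-9)
  }
})

test_that("erf model mass: full sum is N, a 9x9 window captures >= 99%", {
  # wide grid ~ infinite support
  m <- erf_model(60, 60, 3000, 3000, 1234, 0, 150, 100)
  expect_equal(sum(m), 1234, tolerance = 1e-6)
  # (2w+1)^2 window with w = 4 >= 4 s / a holds for s = 100 nm, a = 100 nm
  w9 <- erf_model(9, 9, 450, 450, 1000, 0, 100, 100)
  expect_gte(sum(w9), 0.99 * 1000)
})

test_that("fitting a noiseless model window recovers the generating parameters", {
  win <- model_window(9, x0 = 4.8 * 100, y0 = 4.2 * 100, N = 1000, b = 5,
                      s = 150, a = 100)
  fit <- fit_spot(win, cam100)
  expect_true(fit$converged)
  expect_equal(fit$x_nm, 480, tolerance = 1e-6)
  expect_equal(fit$y_nm, 420, tolerance = 1e-6)
  expect_equal(fit$photons, 1000, tolerance = 1e-5)
  expect_equal(fit$background, 5, tolerance = 1e-6)
  expect_equal(fit$psf_width_nm, 150, tolerance = 1e-6)
  expect_lt(fit$residual_norm, 1e-6 * 1000)
})

test_that("a flat window is flagged not converged", {
  win <- structure(list(pixels = matrix(5, 9, 9), origin = c(col = 0L, row = 0L)),
                   class = "fit_window")
  fit <- fit_spot(win, cam100)
  expect_false(fit$converged)
})

test_that("translating the window content by one pixel shifts the fit by a", {
  base <- erf_model(11, 11, 5.3 * 100, 5.6 * 100, 800, 3, 140, 100)
  win1 <- structure(list(pixels = base[, ], origin = c(col = 0L, row = 0L)),
                    class = "fit_window")
  shifted <- erf_model(11, 11, 6.3 * 100, 5.6 * 100, 800, 3, 140, 100)
  win2 <- structure(list(pixels = shifted, origin = c(col = 0L, row = 0L)),
                    class = "fit_window")
  f1 <- fit_spot(win1, cam100); f2 <- fit_spot(win2, cam100)
  expect_equal(f2$x_nm - f1$x_nm, 100, tolerance = 1e-4)
  expect_equal(f2$y_nm, f1$y_nm, tolerance = 1e-4)
})

test_that("positional accuracy follows the closed form and its scaling law", {
  # no background: sqrt((s^2 + a^2/12) / N)
  expect_equal(positional_accuracy(1000, 0, 150, 100),
               sqrt((150^2 + 100^2 / 12) / 1000), tolerance = 1e-12)
  # quadrupling N halves sigma_loc when b_var = 0
  expect_equal(positional_accuracy(4000, 0, 150, 100),
               positional_accuracy(1000, 0, 150, 100) / 2, tolerance = 1e-12)
  # direct one-line evaluation at the reference setting
  direct <- sqrt((150^2 + 100^2 / 12) / 1000 +
                   8 * pi * 150^4 * 3^2 / (100^2 * 1000^2))
  expect_equal(positional_accuracy(1000, 3, 150, 100), direct, tolerance = 1e-12)
  expect_error(positional_accuracy(0, 3, 150, 100), "N")
})

test_that("background variability: zero on exact model, delta on constructed ring, ~sqrt(mean) on Poisson", {
  win <- model_window(9, 450, 450, 1000, 5, 150)
  fit <- fit_spot(win, cam100)
  expect_lt(background_variability(win, fit), 1e-6)

  # border ring at b +/- alternating delta around an N = 0 model
  px <- matrix(5, 9, 9)
  ring <- c(rep(c(1, -1), 16))
  delta <- 0.8
  px[1, ] <- 5 + delta * ring[1:9]
  px[9, ] <- 5 + delta * ring[10:18]
  px[2:8, 1] <- 5 + delta * ring[19:25]
  px[2:8, 9] <- 5 + delta * ring[26:32]
  fake_fit <- list(x_local_nm = 450, y_local_nm = 450, photons = 0,
                   background = 5, psf_width_nm = 150, pixel_size_nm = 100)
  win2 <- structure(list(pixels = px, origin = c(col = 0L, row = 0L)),
                    class = "fit_window")
  ringvals <- c(px[1, ], px[9, ], px[2:8, 1], px[2:8, 9]) - 5
  expect_equal(background_variability(win2, fake_fit), sd(ringvals), tolerance = 1e-12)
  expect_equal(background_variability(win2, fake_fit), delta, tolerance = 0.02)

  # Poisson background of mean 25: sd of the residual ring ~ 5
  set.seed(7)
  reps <- replicate(200, {
    pz <- matrix(rpois(81, 25), 9, 9)
    wz <- structure(list(pixels = pz, origin = c(col = 0L, row = 0L)),
                    class = "fit_window")
    fz <- list(x_local_nm = 450, y_local_nm = 450, photons = 0,
               background = 25, psf_width_nm = 150, pixel_size_nm = 100)
    background_variability(wz, fz)
  })
  expect_equal(mean(reps), 5, tolerance = 0.1)
})

test_that("Poisson-noise fits track the predicted accuracy and the grid-search oracle", {
  set.seed(42)
  nrep <- 60
  truth <- erf_model(9, 9, 4.3 * 100, 4.6 * 100, 1000, 10, 150, 100)
  xs <- ys <- accs <- rep(NA_real_, nrep)
  wins <- vector("list", nrep)
  for (i in seq_len(nrep)) {
    noisy <- matrix(rpois(81, truth), 9, 9)
    win <- structure(list(pixels = noisy, origin = c(col = 0L, row = 0L)),
                     class = "fit_window")
    fit <- fit_spot(win, cam100)
    if (fit$converged) {
      xs[i] <- fit$x_nm; ys[i] <- fit$y_nm; accs[i] <- fit$accuracy_nm
      wins[[i]] <- list(win = win, fit = fit)
    }
  }
  conv <- !is.na(xs)
  expect_gt(mean(conv), 0.95)
  # mean position within 0.02 px of truth
  expect_lt(abs(mean(xs[conv]) - 430), 2)
  expect_lt(abs(mean(ys[conv]) - 460), 2)
  # empirical std within 25% of the mean predicted accuracy
  emp <- sd(xs[conv])
  expect_lt(abs(emp - mean(accs[conv])) / mean(accs[conv]), 0.25)

  # grid-search oracle on 5 realizations: SSE at the fitted position is no
  # worse than any node of a dense (x0, y0) grid around it
  for (k in which(conv)[1:5]) {
    w <- wins[[k]]$win; f <- wins[[k]]$fit
    sse <- function(x0, y0) sum((w$pixels - erf_model(9, 9, x0, y0, f$photons,
                                                      f$background,
                                                      f$psf_width_nm, 100))^2)
    fit_sse <- sse(f$x_local_nm, f$y_local_nm)
    grid <- expand.grid(x = f$x_local_nm + seq(-50, 50, by = 5),
                        y = f$y_local_nm + seq(-50, 50, by = 5))
    grid_sse <- mapply(sse, grid$x, grid$y)
    expect_lte(fit_sse, min(grid_sse) + 1e-9)
  }
})

test_that("localize_stack recovers a simulated sparse frame set", {
  spec <- scene_spec(geometry = "grid", n_emitters = 4, width_px = 48,
                     height_px = 48, frames = 12, photon_mean = 1500,
                     background_mean = 10, blink_mean_events = 3,
                     blink_mean_on = 4, grid_margin_px = 12, seed = 5)
  sim <- simulate_stack(spec)
  locs <- localize_stack(sim$stack, spec$camera, threshold = 30)
  expect_gt(nrow(locs), 5)
  expect_true(all(locs$uncertainty_nm > 0))
  expect_true(all(locs$frame >= 1 & locs$frame <= 12))
  # every localization lies within 60 nm of a true emitter
  d <- sapply(seq_len(nrow(locs)), function(i)
    min(sqrt((locs$x_nm[i] - sim$truth$emitters$x_nm)^2 +
               (locs$y_nm[i] - sim$truth$emitters$y_nm)^2)))
  expect_lt(median(d), 30)
  expect_lt(max(d), 100)
})
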
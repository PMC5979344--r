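# smlmr

Reconstruction and quantification of two-dimensional single-molecule
localization microscopy (dSTORM) data in R. The package is aimed at
experimentalists who record blinking-fluorophore movies on an EMCCD camera
(e.g. phalloidin-labelled actin in spread platelets) and want to go from a
raw multi-page TIFF to a drift-corrected, super-resolved image plus the
standard structural measurements — all from reproducible, scriptable R code.

The pipeline:

1. **Detection** — per frame, candidate molecules are proposed by thresholded
   non-maximum suppression (Chebyshev radius, deterministic plateau
   tie-break) after a light Gaussian pre-smoothing.
2. **PSF fitting** — each candidate is refined by unweighted least squares
   against the pixel-integrated (error-function) Gaussian PSF. With pixel
   size *a*, PSF width *s* and pixel edge *x_k = k·a*,

   E[k,l] = b + N·ΔE_x(k)·ΔE_y(l),
   ΔE_x(k) = ½ [ erf((x_k + a − x₀)/(√2 s)) − erf((x_k − x₀)/(√2 s)) ],

   fitted over (x₀, y₀, N, b, s) with a trust-region least-squares routine.
3. **Positional accuracy** — each localization carries the predicted standard
   deviation

   σ_loc² = (s² + a²/12)/N + 8π s⁴ b_var² / (a² N²),

   where b_var is the *variability* (standard deviation) of the residual
   background on the fit-window border, not its mean level.
4. **Marker-less drift correction** — localizations are grouped (equal frame
   blocks or equal point counts); each group is registered to the
   accumulated basis set by maximizing the Parzen-window cost

   CF(d) = Σ_j Σ_i 1/(2πσ²) · exp(−‖p_j + d − p_i‖² / 2σ²)

   over translations d (coarse grid scan + quasi-Newton ascent, shift
   increments capped at 3× the median fit accuracy). The raw per-group
   shifts are smoothed by a cubic smoothing spline (fidelity/roughness
   parameter p, 10⁻⁴ windowed / 10⁻⁶ global) and applied per frame.
5. **Rendering** — every molecule is drawn as a symmetric Gaussian with
   σ = its positional accuracy; brighter areas mean more localizations.
6. **Quantification** — cross-section Gaussian fits (FWHM = 2√(2 ln 2)·σ)
   for filament widths, localization density per µm² inside a polygon ROI,
   and blinking-event statistics (spatial single-linkage clustering, gap
   merging).
7. **Simulation** — a first-class generator of blinking emitters on defined
   geometries with erf-model spots, Poisson shot noise, EMCCD gain/offset/
   read noise and linear stage drift, with full ground truth, so every stage
   is testable without real acquisitions.

## Worked example

```r
library(smlmr)

# Simulate a 1,000-frame acquisition of 16 blinking emitters with 40 x -25 nm
# stage drift, then reconstruct it.
spec <- scene_spec(geometry = "grid", n_emitters = 16, width_px = 64, height_px = 64,
                   frames = 1000, photon_mean = 1000, background_mean = 10,
                   blink_mean_events = 9, blink_mean_on = 3,
                   drift_nm = c(40, -25), grid_margin_px = 10, seed = 7)
sim  <- simulate_stack(spec)
locs <- localize_stack(sim$stack, spec$camera, threshold = 25)
locs
#> # A tibble: 407 × 7
#>   frame  x_nm  y_nm photons background_photons sigma_psf_nm uncertainty_nm
#> 1     6 3930.  985.   1032.               9.98         158.           6.58
#> 2     7 5401. 5396.   1048.               8.83         154.           6.09
#> ...

corr <- correct_drift(locs, drift_config(group_mode = "frames", group_size = 100))
glance(corr)
#>   n_localizations n_groups n_capped kernel_sigma_nm max_drift_nm track_rms_nm
#> 1             407       10        0            6.08         18.2         26.4

render(corr$localizations, out_pixel_size = 10)
#> <smlm_image> 449 x 449 px at 10 nm/px, total intensity 407
```

407 molecules were fitted with a median predicted accuracy of ~6 nm per
axis; the recovered drift track has 26 nm RMS amplitude (the injected ramp),
and the rendered image integrates to one unit of mass per localization.

Width of a simulated filopodium (true FWHM 115 nm, localized at 12 nm
accuracy — the fitted width is the truth broadened by the localization
error in quadrature, ≈118 nm):

```r
fspec <- scene_spec(geometry = "filopodium", n_emitters = 2400, frames = 2000,
                    line = c(1000, 3000, 5000, 3500), transverse_sigma_nm = 48.83,
                    accuracy_nm = 12, blink_mean_events = 1, blink_mean_on = 1, seed = 1)
floc <- simulate_localizations(fspec)$localizations
fit  <- fit_profile_fwhm(cross_section_profile(floc, c(1000, 3000, 5000, 3500)))
fit
#> <smlm_profile_fit> FWHM 124.3 nm (sigma 52.8 nm), center -0.9 nm
```

Blinking statistics over a 15,000-frame sequence (9 events/emitter
configured):

```r
bspec <- scene_spec(geometry = "grid", n_emitters = 36, frames = 15000,
                    blink_mean_events = 9, accuracy_nm = 10, grid_margin_px = 6, seed = 2)
blinking_events(simulate_localizations(bspec)$localizations,
                link_radius = 50, max_gap = 0)
#> <smlm_blinking> 36 molecules: 9.2 +/- 3.2 events (SD; SEM 0.54)
```

All result objects support `tidy()`, `glance()`, `augment()` (profile fits)
and `autoplot()`. A thin shell entry point with subcommands
`simulate | localize | driftcorr | render | quantify | run` is installed at
`inst/cli/smlm`; `run_pipeline()` drives the whole chain from one YAML
config and writes a run log with every effective parameter.

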
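---
title: "Models and methods behind smlmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smlmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smlmr)
```

This vignette is the package's own account of its science: the models each
stage implements, the assumptions behind them, the tunable parameters and
their defaults, what the synthetic-data generator does and does not emulate,
and the numerical choices made where the design was genuinely open.

## The measurement problem

In dSTORM, photo-switchable fluorophores blink sparsely, so each camera frame
contains a handful of isolated single-molecule images. Fitting each image
yields the molecule position far below the diffraction limit; accumulating
positions over thousands of frames reconstructs the labelled structure. Two
systematic effects dominate the error budget of a long acquisition: the
finite photon count per blink (statistical localization error) and the slow
mechanical drift of the stage (a correlated, global error). The package
implements the full chain — detection, fitting, accuracy estimation,
marker-less drift correction, rendering and quantification — plus a
simulator that generates ground-truth data under the same acquisition model
(100 nm pixels, 20 ms exposure at 25 frames/s, 15,000-frame sequences, about
9–10 blinking events per fluorophore per sequence).

## Coordinates and units

All continuous positions are in nanometres, with the origin at the outer
corner of pixel (0, 0): the center of (0-based) pixel (col *k*, row *l*) is
at $x = (k + 0.5)a$, $y = (l + 0.5)a$, where $a$ is the pixel size. This
puts pixel *edges* at integer multiples of $a$, which is exactly what the
integrated-Gaussian model needs. Frames are 1-based in all tables. Camera
counts (ADU) convert to photons by the affine model
$\text{photons} = \max(0, (\text{ADU} - \text{offset})/\text{gain})$; gain
and offset are acquisition metadata the camera file does not carry, so they
are required configuration.

## Detection

Candidates are local maxima of the (optionally pre-smoothed) photon frame:
a pixel survives when it is at least `threshold` photons and strictly
dominates every neighbour within Chebyshev distance `radius` (default 3 px).
Equal-valued plateaus are resolved deterministically in favour of the
lexicographically smallest (row, col), so exactly one candidate per plateau
survives and repeated runs produce identical output. The pre-smoother
(default $\sigma$ = 1 px) is a truncated Gaussian kernel renormalized per
pixel at the borders; renormalization preserves constants exactly, which
gives the useful invariance that adding a constant to the frame and to the
threshold leaves the candidate set unchanged. Detection thresholds are
expressed in photons *above the frame median*, so a slowly varying
background level does not require per-frame retuning. Candidates closer
than half a fit window to the border are dropped — they cannot be fitted on
a complete window.

## PSF model and fitting

A molecule image is modelled as a symmetric 2-D Gaussian of width $s$
integrated over the square pixels (the error-function model), with expected
photons $E[k,l] = b + N\,\Delta E_x(k)\,\Delta E_y(l)$ and

$$\Delta E_x(k) = \tfrac12\left[\operatorname{erf}\!\Big(\frac{x_k + a - x_0}{\sqrt2\,s}\Big)
 - \operatorname{erf}\!\Big(\frac{x_k - x_0}{\sqrt2\,s}\Big)\right].$$

$N$ is the *total* expected photon count ($\sum_k \Delta E_x(k) \le 1$), $b$
a flat background per pixel. The objective is unweighted least squares over
$(x_0, y_0, N, b, s)$, matching the model's reference lineage; a
Poisson-weighted (maximum-likelihood) estimator is deliberately out of
scope. The optimizer contract is "trust-region least squares": the package
uses the Levenberg–Marquardt trust-region implementation in `minpack.lm`,
and the contract is enforced by the exact-model fixed-point test (a
noiseless model window must be recovered to optimizer tolerance, residual
norm below $10^{-6}$ of the signal).

Numerical choices:

* Initialization: position at the candidate pixel center, background at the
  window-border median, $N$ at (window sum − b·area), $s = 1.3a$.
* Bounds: $s \in [0.5a, 4a]$; fits ending on those bounds are flagged not
  converged (rejects fused doublets and hot pixels). Position must stay
  inside the window, $N > 0$.
* Window half-width $w = 4$ (9×9 pixels) by default for $a = 100$ nm —
  large enough to hold ≥ 99 % of the blob mass for $s \lesssim a$ and a
  clean background ring, small enough to keep neighbouring molecules out.
* Convergence: relative objective decrease below $10^{-8}$ or 200
  iterations; flat windows are rejected up front.

## Positional accuracy

Each converged fit carries the predicted standard deviation

$$\sigma_{loc}^2 = \frac{s^2 + a^2/12}{N} + \frac{8\pi s^4\, b_{var}^2}{a^2 N^2},$$

with $b_{var}$ the *background variability*: the standard deviation of
(data − model) over the one-pixel border ring of the fit window. Using the
variability rather than the mean background level matters — a bright but
uniform background harms the fit far less than a noisy one.

A calibration caveat, measured by the package's own acceptance checks: for
*unweighted* least squares the formula's background term assumes uniform
noise, while Poisson noise is strongest under the peak. At the reference
configuration ($N = 1000$, $b = 10$, $s = 150$ nm, $a = 100$ nm) the robust
(sandwich) variance of the unweighted estimator is about 20–25 % larger than
the formula predicts, and the empirical RMSE of simulated fits sits at the
upper edge of that band. The prediction is therefore a slightly optimistic
per-molecule error bar, adequate for rendering widths and for drift-kernel
scaling, but not a guarantee of estimator efficiency.

## Marker-less drift correction

Stage drift is estimated directly from the localization set. Localizations
are partitioned into groups either by equal frame blocks (default 500
frames) or by equal point counts ("points" mode, which equalizes statistical
power at the cost of variable time spans). The first group initializes a
basis set; each subsequent group is registered to the accumulated basis by
maximizing the Parzen-window cost

$$CF(d) = \sum_j \sum_i \frac{1}{2\pi\sigma^2}
  \exp\!\left(-\frac{\lVert p_j + d - p_i\rVert^2}{2\sigma^2}\right)$$

over translations $d$; the shifted group is then merged into the basis and
the process repeats. Only translation is corrected — rotation of a
well-centered field is negligible over these sequences and is out of scope.

Design choices that the source description leaves open, and how they were
resolved:

* **Kernel width** $\sigma$ defaults to the median fitted accuracy of the
  input set: the kernel should match the scatter of repeated localizations
  of one molecule, and that scatter *is* the positional accuracy.
* **Optimization**: the cost surface is multi-modal (every pairing of
  molecules creates a local bump), so the quasi-Newton (BFGS) ascent is
  started from the best node of a coarse grid spanning ±3σ in steps of σ/2
  around the previous group's shift. The returned shift never scores below
  the best grid node.
* **Warm start and cap**: drift accumulates, so late groups legitimately sit
  many multiples of σ away from the basis. Each group's search therefore
  starts from the previous group's shift, and the "max-limit-drift" cap
  (3 × median fit accuracy, flaggable per group) bounds the *increment*
  relative to that start — physically, the drift added during one group
  interval. For a standalone registration (zero start) this reduces to a
  cap on the absolute shift length. Groups with fewer than 3 points carry
  the previous shift forward with a warning.
* **Track assembly**: each group's shift is anchored at its mid-frame; the
  resulting raw track is smoothed by a cubic smoothing spline and evaluated
  at every frame (knots at the group mid-frames — pre-interpolating to all
  frames would only add knots without changing the fit), then added to every
  localization. Record counts and all non-positional fields are preserved,
  and all localizations of one frame are translated rigidly.

### Smoothing-spline convention

The spline minimizes $p\sum_i (y_i - f(t_i))^2 + (1-p)\int f''(t)^2\,dt$
with $p \in (0,1)$ and $t$ in frames — the classic fidelity/roughness
trade-off in which $p \to 1$ interpolates and $p \to 0$ yields the
least-squares straight line. The defaults are $p = 10^{-4}$ inside sliding
windows (default 1,000 frames, advancing by half a window, overlapping
estimates averaged) and $p = 10^{-6}$ for one global fit. The abscissa is
*not* rescaled, so these magnitudes mean what they say on the frame axis;
this is why the solver is implemented in the package (the Reinsch band
system $(R + \lambda Q^\top Q)c = Q^\top y$, $\lambda = (1-p)/p$) rather
than via `stats::smooth.spline`, whose internal x-rescaling changes the
meaning of the parameter. The implementation is verified against a
discretized quadratic-program oracle and both closed-form limits.

Global smoothing suits a slow, sequence-long ramp; windowed smoothing
follows faster meanders at the cost of more variance. Both are exposed;
global is the default because the drift being corrected is, to first order,
linear.

## Rendering

Each localization is drawn as a symmetric 2-D Gaussian centered at its
position with σ equal to its accuracy, integrated over the output pixels
(blob mass is then exact, not approximate) and truncated at 5σ (relative
mass error < 10⁻⁶ per blob). Unit mode gives every molecule mass 1, so
image brightness is localization density; photons mode weights by the
fitted photon count. The default output pixel (10 nm) comfortably samples a
~12 nm accuracy. No gamma or clipping is applied — display scaling belongs
to the viewer. Because CRAN's `tiff` writer stores float samples in [0, 1],
rendered images are written normalized with the absolute scale in a YAML
sidecar; `read_render()` restores the image exactly.

## Quantification

**Cross-section width.** Localizations within a band around a user-drawn
axis are projected onto its normal and histogrammed (default 10 nm bins,
300 nm half-band); a Gaussian-plus-offset least-squares fit gives
FWHM $= 2\sqrt{2\ln 2}\,\sigma \approx 2.3548\,\sigma$. Working on
localization offsets rather than the rendered image avoids render-pixel
quantization; an image-based method is provided for comparison with
diffraction-limited profiles. A structure of true width FWHM₀ measured at
accuracy σ_loc appears broadened to
$\sqrt{\text{FWHM}_0^2 + (2.3548\,\sigma_{loc})^2}$ — the package's FWHM
checks test against this quadrature-broadened truth. Note the effective
sample size of a width estimate is the number of *distinct* fluorophores,
not localization records: re-lighting the same molecules adds no new
transverse information, which is why the validation scenes use many
emitters with a single short event each.

**Density.** Localizations strictly inside a user-supplied simple polygon,
divided by its shoelace area, per µm². Automatic cell segmentation is out
of scope.

**Blinking.** Records are clustered into putative molecules by single
linkage within `link_radius` (default 50 nm ≈ 4× a typical accuracy);
within a molecule, consecutive-frame runs separated by gaps of at most
`max_gap` off-frames merge into one event. The summary reports mean, SD
over molecules and SEM. No linking rule is canonical; both parameters are
exposed, and recovery is exact on simulated data when the gap rule matches
the generator.

## The simulator

`simulate_stack()` draws, per emitter, a Poisson number of blinking events
(default mean 9 per sequence), uniform start frames and geometric
on-durations (default mean 3 frames, overlaps merged); while on, the
emitter contributes an erf-model spot (same forward model the fitter uses)
of `photon_mean` expected photons (default 1,000 over a background of 10
photons/pixel — a budget that yields roughly 12 nm combined localization
error) at its true position plus the frame's cumulative linear drift. The
photon image is Poisson-sampled and converted to ADU with gain, offset and
Gaussian read noise, clipped to the unsigned 16-bit range.
`simulate_localizations()` bypasses the image stage and emits records with
isotropic Gaussian jitter of a stated accuracy, which isolates drift
correction and quantification from detection and fitting. Geometries:
uniform fields, filament lines with Gaussian transverse scatter
(filopodium-like), rings (peripheral-band-like) and bead grids. One seed
fixes the entire stream; the same spec reproduces bit-identical stacks.

What the simulator does *not* emulate — and hence what passing tests do not
show about real data: EMCCD excess (multiplicative) noise, so real photon
counts are effectively noisier than simulated ones at equal gain;
dye photophysics beyond Poisson event counts and geometric on-times (no
dark-state kinetics, no bleaching trend across the sequence); structured
cellular background; out-of-focus light and PSF aberrations; multi-emitter
overlap beyond what sparse blinking produces. Conclusions about absolute
detection efficiency or absolute photon budgets on real acquisitions should
not be drawn from the simulations alone.

## Validation scales

The test suite and the acceptance script run at desk scale, chosen so the
statistics are informative while the whole suite stays fast: oracle
equivalences on 64×64 frames (100 seeds) and 20×30-point sets; accuracy
tracking on 200 Poisson realizations of the reference spot; drift recovery
on 2,000-frame, 150-emitter sequences (100 × −60 nm ramp and a drift-free
control against the ~3 nm instrument-stability floor); FWHM recovery on
≥ 2,000 independent transverse draws; and an end-to-end
simulate → localize → correct → render → quantify chain on a 2,000-frame,
64×64 scene. Paper-scale sequences (15,000 frames) are used only where the
quantity is defined per sequence (blinking statistics).

## Known limitations

* The accuracy formula slightly under-predicts the scatter of the
  unweighted least-squares fitter (see above); a Poisson-weighted estimator
  would close the gap but is out of scope.
* Drift correction assumes enough localizations per group to register
  reliably (≥ tens); extremely sparse channels need larger groups or
  "points" mode.
* The sequential basis set grows without bound; memory is no concern at
  typical set sizes (10⁴–10⁵ records), but the cost of late-group
  registrations grows linearly with the accumulated set.
* Single-linkage blinking clustering assumes molecules are separated by
  more than `link_radius`; dense structures bias event counts upward (the
  per-molecule table makes this visible).
* No multi-emitter fitting, no 3-D/astigmatic PSF, no sCMOS per-pixel noise
  model.
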
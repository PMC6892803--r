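---
title: "Localization-based super-resolution thermography: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localization-based super-resolution thermography: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoloc)
```

## The imaging problem

Far-infrared thermography reads temperature directly — the gray-body law
$R = \varepsilon \sigma T^4$ converts the radiance collected by a
microbolometer array into degrees — but its spatial resolution is poor:
diffraction at the low-NA germanium optics limits it to roughly
$\lambda/(2\,\mathrm{NA}) \approx 345\ \mu m$ for 7–14 µm thermal
wavelengths, and lateral heat diffusion in the sample degrades the
*effective* resolution to the millimetre scale.

`thermoloc` implements (and simulates end-to-end) a way around this limit
borrowed from single-molecule localization microscopy. A focused visible
laser beam (1/e² diameter 22–56 µm) is raster-scanned over the sample,
but the shutter only opens on a sparse square lattice of scan pixels per
pass, so each laser-induced temperature spot appears isolated in the
camera movie. Each isolated spot, although hundreds of micrometres wide on
the camera, has a *center* that can be fitted to a few tens of micrometres
— limited by photon shot noise, not by diffraction. Repeating the scan
$\Delta_x \Delta_y$ times covers every scan pixel once; the fitted centers
and amplitudes, binned back onto the scan grid, form a super-resolved map
of the absorptive centers with pixel size $\delta x \sim 10$–100 µm.

## Forward model

### Heat deposition and transport

A pulse of duration $\tau_{on}$ centered at $\mathbf r_0$ deposits heat at
rate

$$ q(\mathbf r) = A \, m(\mathbf r)\, e^{-2|\mathbf r - \mathbf r_0|^2 / w_0^2}, $$

where $m$ is the absorptance map (0–1), $w_0$ the 1/e² beam radius, and
$A$ (°C/s) a lumped heating amplitude absorbing laser power, heat
capacity and section thickness. Each deposited increment then evolves by
two-dimensional in-plane diffusion (heat kernel of variance $2 D a$ per
axis at age $a$) and by Newton cooling into the substrate and the
environment, $e^{-a/\tau_d}$:

$$ \Delta T(\mathbf r, t) = A \int_0^{\min(t - t_0,\, \tau_{on})}
   \left[ m(\cdot)\, e^{-2|\cdot - \mathbf r_0|^2/w_0^2} \ast
   K_{2 D a} \right](\mathbf r)\; e^{-a/\tau_d} \, du,
   \qquad a = t - t_0 - u. $$

This reproduces every qualitative behaviour the method rests on: an
approximately Gaussian spot, exponential-like rise and decay with the
maximum exactly at $\tau_{on}$, diffusive broadening, and linearity in
$A$ and in the map. For a uniform absorber and $D = 0$ the closed forms
are exact ($\Delta T = A \bar a\, \tau_d (1 - e^{-\tau/\tau_d})$ at the
beam center, a pure beam-profile Gaussian in space) and are frozen into
the unit tests. Crucially, because the source is the *pointwise product*
of map and beam profile, a beam parked on an absorber edge produces a
spot whose fitted center sits at the beam-intensity-weighted centroid of
the absorber — the physical basis for localizing structure smaller than
the beam, verified against a numerical centroid oracle in the tests.

The emission-time integral is evaluated by fixed-step trapezoid
quadrature with step $\le \tau_{on}/50$; once every contributing
increment is old (ages $\gg \tau_{on}$, during the decay tail) the
integrand is smooth in $u$ and eight nodes suffice. An event stops
contributing to a frame when a conservative analytic bound on its
residual camera-plane amplitude falls below $10^{-3}$ °C (1% of the
camera sensitivity); the bound, not a relative decay factor, is used so
that slowly fading tails — which raise the scene background by several
tenths of a degree — are never silently truncated.

### Camera

The camera samples the field at `f_rate` (default 30 Hz, 320 × 240
format, 400 µm pixels on the sample plane). The optical PSF (Gaussian,
FWHM 345 µm by default — the diffraction-limited prediction) and the
pixel box average are applied analytically: every source cell is a point
source whose blurred image is a Gaussian, whose box integral is a
product of error functions. This is exact (it is the limit of infinite
supersampling) and keeps rendering fast enough to simulate full scans in
seconds.

Two noise models are provided:

* **`netd`** — i.i.d. Gaussian noise of standard deviation `netd`
  (default 0.1 °C, the camera sensitivity);
* **`photon`** — each pixel's excess radiance is linearized as
  $4 \varepsilon \sigma T_0^3\, \Delta T$, converted to expected photon
  counts, Poisson-sampled together with a background of `background`
  photons, and mapped back to temperature. This makes the localization
  error scale with the collected photon number, which is what the
  precision law below assumes.

The linearization is excellent in the regime of interest: at
$T_0 = 293$ K it underestimates the exact quartic difference by 1% for
$\Delta T = 2$ K and stays below 5% up to 10 K
(`photon_linearization_error()`).

### Photon-budget defaults

Experimental calibrations of localization uncertainty against peak
amplitude in this imaging regime take the form
$\sigma \approx \sqrt{\alpha/\Delta T + \beta/\Delta T^2}$ with
$\alpha \approx 600$ °C µm². The default
`photon_gain = 11.4` photons per (W m⁻²) per pixel per frame anchors the
synthetic camera to that value: with the default ink sample and 22 µm
beam the fitted spot width is $\zeta \approx 230$ µm, giving
$(\zeta^2 + a^2/12) / N \approx \alpha/\Delta T$ with
$N \approx 120\,\Delta T$ photons. The background default of 2 photons
per pixel per frame is chosen inside the regime where the analytic
background term $4\sqrt{\pi} b^2 \zeta^3/(a N^2)$ matches the actual
contribution of Poisson background noise to the fit scatter (the term is
quadratic in $b$ while the sampling noise is linear, so they agree only
in a band around a few photons). As a consequence the synthetic $\beta$
is smaller than a physical camera's, whose background includes
non-Poisson readout components; the *shape* of the law, which is what
the method relies on for extrapolating error bars, is reproduced across
the full 0.5–4 °C amplitude range.

### Sample presets

| preset | ε | D (µm²/s) | τ_d (s) | rationale |
|---|---|---|---|---|
| `sample_ink()` | 0.8 | 1.0 × 10⁵ | 0.15 | printed ink on polymer film |
| `sample_biopsy()` | 0.95 | 1.3 × 10⁵ | 0.15 | water-rich 10 µm tissue section |

Diffusivities are typical of polymer film and of water (1.43 × 10⁵
µm²/s); the common loss time reflects fast Newton cooling of a ~10 µm
section into its substrate. This fast relaxation is what makes the
sequential protocol feasible at all: activations are only
$\tau_{on} \approx 0.3$ s apart, so a pulse's residual must decay within
a few tenths of a second for the next peak to be fitted cleanly. The
heating amplitudes `A` are order-of-magnitude placeholders; every
simulation in the tests and examples rescales `A` with
`calibrate_amplitude()` so that the *camera-fitted* amplitude hits a
stated target (0.3–5 °C, the experimentally relevant range) — mirroring
the experimental practice of tuning laser power and pulse length to a
desired signal level.

## Scan protocol

`scan_protocol()` + `build_schedule()` produce the ordered pulse list:
scan $s$ activates pixels congruent to the $s$-th lattice offset
(row-major order over offsets — the choice is arbitrary and recorded in
the schedule), the laser dwells $\tau_{on}$ on activated and $\tau_{off}$
(default 2 ms) on silent pixels, and the closed-form total time

$$ t_{tot} = N_x N_y \tau_{on} + N_x N_y \tau_{off} (\Delta_x \Delta_y - 1) $$

equals the traversal end of the schedule (exactly so for
lattice-commensurate grids, $\Delta_x | N_x$, $\Delta_y | N_y$, which the
package's own studies use). `min_separation()` encodes the
diffusion-length heuristic for how far apart concurrent spots must be,
$\Delta x_{min} = k\sqrt{w_0^2/4 + 4 D \tau_{on}}$ and
$\Delta t_{min} = k \max(\tau_{on}, \tau_d)$ with a default safety factor
$k = 3$; `validate_schedule()` reports violating pairs rather than
refusing to run, since the criterion is deliberately conservative: with
fast cooling, temporally adjacent pulses are separable well inside
$\Delta t_{min}$.

## Peak detection

For every camera pixel in the region of interest (found by thresholding
the temporal maximum projection at 3 NETD above the baseline estimate), a
window of `max(5, round(2 * tau_on * f_rate))` frames slides along the
trace one frame at a time, and a 1-D Gaussian *on a linear baseline* is
fitted at each position. The linear term absorbs the slowly decaying warm
background left by earlier pulses; without it, peaks riding on the drift
are widened or displaced. A candidate is accepted when

* the fitted center lies in the central third of the window,
* the fitted amplitude reaches the threshold (default 3 NETD = 0.3 °C,
  matching the rendering threshold used for treated samples),
* the fitted width lies between `window/8` and `window/3` frames —
  rejecting one-sample noise spikes and baseline-wide pseudo-peaks whose
  amplitude is degenerate with the free baseline,

and candidates closer than half a window merge keeping the larger
amplitude. Merged peaks supported by a *single* window position are
discarded: a real transient is re-found at several consecutive positions,
a noise excursion is not. Under these rules, flat traces with NETD noise
at the default threshold yield fewer than one false peak per 10⁴ frames.
The stored peak time is the raw local maximum near the fitted center
(the symmetric Gaussian approximates an asymmetric rise/decay, so its
center is slightly early; the raw maximum is not). Detections from the
same pulse seen in neighbouring pixels (frames within ±1, pixels
8-connected, transitively) merge into one event represented by the
largest-amplitude pixel.

## Localization

The frame at each event's peak is fitted over an 11 × 11-pixel window by
the **two-step symmetric Gaussian fit**: step 1 fixes the spot variance
at the clean forward-model value
$\zeta_0^2 = w_0^2/4 + 2 D \tau_{on} + \sigma_{PSF}^2$
(`default_zeta0_sq()`, configurable) and frees center, amplitude and
offset; step 2 fixes the center and frees variance, amplitude and
offset. Free symmetric, asymmetric, and per-axis skew-normal surfaces
are provided for comparison; on the package's synthetic data the
two-step fit has the smallest center scatter of the four (the skew fit, with its location–skewness degeneracy,
is dramatically worse). The closed-form precision law

$$ \sigma_{x,y} = \sqrt{ \frac{\zeta^2 + a^2/12}{N}
   + \frac{4\sqrt{\pi}\, b^2 \zeta^3}{a N^2} } $$

is attached to each localization, with $N$ inferred from the fitted
amplitude via the linearized gray-body gain and the effective number of
spot pixels $2\pi\zeta^2/a^2$. Note the law describes a *free* Gaussian
fit; the constrained two-step estimator consistently beats it by
20–30%, which is precisely why it is the default. For real data, where
the photon gain is unknown, `calibrate_alpha_beta()` fits
$\sigma^2 = \alpha/\Delta T + \beta/\Delta T^2$ to measured
repeatability points (non-negative least squares on the two basis
functions) and `sigma_vs_deltaT()` extrapolates the uncertainty to any
measured amplitude.

## Reconstruction and assessment

`bin_localizations()` assigns each fitted center to its scan pixel
(half-open, zero-based, origin-anchored bins), keeps the **largest**
amplitude per pixel, and zeroes pixels below `dT_min` (default 0.3 °C;
0.1 °C — the camera sensitivity — for untreated controls). The image
value is the temperature *increment*; an absolute mode is a matter of
adding `T0`. `max_projection()` gives the conventional low-resolution
image from the same stack for comparison, and `overlay_report()`
quantifies co-localization with the ground truth as the fraction of
rendered pixels within a radius of any absorbing cell — either one
scalar radius or a per-pixel radius (typically twice the per-pixel
predicted σ, mirroring the practice of extrapolating each point's error
bar from the σ-versus-ΔT curve).

Resolution is quantified on line profiles (`extract_profile()`, bilinear
sampling with perpendicular averaging) via the dip contrast between
adjacent maxima, $100 (\bar p - d)/\bar p$. This definition is the one
under which two equal incoherent Airy patterns separated by the first
zero give the canonical threshold — `rayleigh_contrast_threshold()`
computes 26.5% from the Bessel integral, and the tests record that the
symmetric alternative $(max-min)/(max+min)$ would give ~15% instead and
is therefore rejected. A 3-sample moving mean (configurable off) smooths
profiles before extrema detection, and an optional minimum peak
separation merges sampling ripples on top of a broad stripe so they are
not mistaken for structure.

## Synthetic study conditions

The package's end-to-end validation simulations use deliberately
compact scenes and scan grids — small enough to re-run routinely, large
enough that every stage of the method is exercised under realistic
noise; the sizes are the package's own choices:

* **Repeatability / precision law** — 150 pulses on a uniform 800 µm ink
  square, 22 µm beam, photon noise, camera amplitudes 0.5–4 °C.
* **Stripe resolution** — five 60 µm stripes with 60 µm gaps; 36 × 16
  scan pixels at δx = 10 µm, lattice (9, 4), τ_on = 0.3 s (≈ 6 400
  frames at 30 Hz); the super-resolved vertical-mean profile resolves
  adjacent stripes (120 µm apart) above the 26.4% Rayleigh contrast
  while the max projection of the same stack shows no structure.
* **Sparse clusters / specificity** — five 60 µm-radius absorbing disks
  in a 700 × 400 µm field, 32 × 16 scan pixels at δx = 20 µm; rendered
  pixels co-localize with the truth at twice the per-pixel predicted σ
  in ≥ 95% of cases across seeds, and a cluster-free control renders
  zero pixels at `dT_min` = 0.3 °C.

## What the generator does and does not emulate

The synthetic stacks reproduce Gaussian temperature spots with
exponential-like rise and decay on the real camera geometry (400 µm
pixels, 30 Hz, 0.1 °C sensitivity), photon shot noise scaling with the
temperature increment, the modulated lattice schedule, and diffusive
spot broadening. They do **not** emulate: three-dimensional conduction
into the substrate beyond the lumped Newton term; emissivity
heterogeneity (supported as an optional per-position factor, default
uniform); camera fixed-pattern noise, vignetting, or finite exposure
(frames are instantaneous samples — integration time is not part of the
camera description); atmospheric or reflected-ambient corrections
(assumed already applied in firmware, as for real exported data). A
passing test suite therefore validates the analysis chain and its
statistical behaviour under the stated noise models, not the thermal
physics of any particular specimen.

## Numerical choices and limitations

* Nonlinear fits use Levenberg–Marquardt (`minpack.lm`), parameter and
  function tolerances 10⁻¹⁰, 200 iterations; iteration-capped fits are
  accepted with their best-found parameters (this occurs essentially
  only in the skew model's flat λ ≈ 0 valley).
* Fit windows clipped at frame edges proceed when at least 7 pixels per
  axis remain; smaller windows drop the event, counted in the run log.
* Stacks are written as 32-bit TIFF linearly rescaled to [0, 1] with the
  scale in a JSON sidecar (the format stores 32-bit pages as scaled
  integers); round trips are exact to ~10⁻⁹ relative.
* Localizations outside the scan grid (edge events pulled outward by
  noise or by absorber structure beyond the grid) are dropped and
  counted, as are fit failures; raising `dT_min` can only remove
  rendered pixels.
* The per-pixel trace analysis assumes at most one laser pulse
  contributes a *peak* to a given window; overlapping multi-emitter
  unmixing is out of scope.
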
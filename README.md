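# thermoloc

Sub-diffraction thermal imaging by localization of laser-induced
temperature peaks — simulation and analysis in R.

## The problem

Far-infrared thermography measures temperature quantitatively (gray-body
law *R* = εσ*T*⁴, ~0.1 °C sensitivity) but resolves poorly: diffraction
at low-NA thermal optics limits resolution to ~345 μm, and lateral heat
diffusion degrades it to the millimetre scale in practice. Yet many
applications — mapping photothermal nanoparticles in tissue sections,
characterizing printed absorber patterns, thermal screening — need tens
of micrometres over millimetre fields of view.

The way out mirrors PALM/STORM localization microscopy. A focused
visible laser (1/e² diameter 22–56 μm) raster-scans the sample, with the
shutter opened only on a sparse square lattice of scan pixels per pass so
every laser-induced temperature spot appears *isolated* in the thermal
camera movie. Each spot is hundreds of micrometres wide on the camera,
but its **center** can be fitted far more precisely:

σ<sub>x,y</sub> = √( (ζ² + a²/12)/N + 4√π b²ζ³/(aN²) ) ≈ √( α/ΔT<sub>max</sub> + β/ΔT<sub>max</sub>² )

with ζ the fitted spot width, *a* the camera pixel size, *N* the
collected thermal photons (∝ 4εσT₀³ΔT by the linearized gray-body law)
and *b* the background photons. Repeating the scan Δx·Δy times covers
every pixel; the fitted centers, binned on the scan grid δx and
color-coded by the largest amplitude ΔT<sub>max</sub> per pixel (above a
threshold ΔT<sub>min</sub>), form the super-resolved absorber map.

`thermoloc` implements the complete chain, for both synthetic stacks it
generates itself and real camera exports (per-frame CSV or multi-page
TIFF): scene fixtures with ground truth, modulated scan schedules and
their timing model, a heat-diffusion + Newton-cooling forward simulator
with NETD or photon shot noise, sliding-window 1D peak detection in
per-pixel traces, two-step 2D Gaussian localization with the closed-form
and empirical precision laws, scan-grid binning, and resolution
assessment against the first-principles Rayleigh 26.4% dip-contrast
threshold and the Abbe limit.

## Worked example

Simulate a scaled stripe target (three 60 μm ink stripes, 60 μm gaps),
image it with the modulated protocol, and reconstruct:

```r
library(thermoloc)

map    <- make_stripe_grid(60, 60, 3, pitch = 5)     # three 60 um ink stripes
beam   <- beam_model(diameter_1e2 = 22, power = 15)
camera <- camera_flir_e40(format = c(16, 12))        # small cut-out of the sensor
proto  <- scan_protocol(24, 12, 10, lattice = c(6, 4), tau_on = 0.3,
                        origin = c(60, 150))
sample <- calibrate_amplitude(map, sample_ink(), beam, camera,
                              location = unlist(map$centers[1, ]),
                              tau_on = 0.3, target_dT = 1.5)
schedule <- build_schedule(proto)
proto
#> scan_protocol: 24 x 12 px at 10 um, lattice (6, 4), tau_on 0.3 s, tau_off 0.002 s
#>   24 scans, 12 events/scan (if commensurate), t_tot 99.65 s

stack <- render_stack(map, sample, beam, schedule, camera,
                      noise = "photon", seed = 1)
stack
#> thermal_stack: 3020 frames of 12 x 16 px (400 um) at 30 Hz, T0 = 19.9 degC

events <- detect_stack_events(stack, window = default_window(0.3, 30),
                              amp_threshold = 0.3)
locs <- localize_events(stack, events,
                        zeta0_sq = default_zeta0_sq(sample, beam, camera, 0.3),
                        sample = sample)
head(round(locs[, c("x_c", "y_c", "sigma_x", "dTmax", "zeta2")], 1), 3)
#>     x_c   y_c sigma_x dTmax   zeta2
#> 1  27.9 100.3    21.4   1.5 47957.7
#> 2 150.0 147.2    22.2   1.3 54469.8
#> 3 231.9 131.2    22.1   1.3 55972.2

sr <- bin_localizations(locs, proto, dT_min = 0.3)
sr
#> superres_image: 12 x 24 px at 10 um, dT_min 0.3 degC, 90 filled px (119 locs outside grid)

prof <- extract_profile(sr, start = c(60, 210), end = c(300, 210), width = 120)
adjacent_peak_contrast(prof, min_separation = 60)
#>   pos_a pos_b    peak_a    peak_b       dip contrast
#> 1    30   150 0.6810768 0.7401924 0.1721083 75.78104
```

The localizations land on the stripes with ~20 μm predicted uncertainty
(camera pixels are 400 μm — a twenty-fold finer scale), and the vertical
mean profile of the reconstruction separates the two stripe centers
(120 μm apart) with 76% dip contrast, far above the 26.4% Rayleigh
threshold — while the same stack's maximum projection, the conventional
thermal image, shows a single unresolved blob. The dropped "outside
grid" localizations are edge events pulled beyond the small scan window;
they are counted, not silently discarded.

A YAML-configured end-to-end run (simulate → detect → localize → render
→ report, all artifacts written to disk) is available as
`run_pipeline()` or from the shell:

```sh
Rscript scripts/thermoloc.R pipeline --config examples/run.yaml --out out/ --seed 1
```

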
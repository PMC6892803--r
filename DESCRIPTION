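Package: thermoloc
Title: Sub-Diffraction Thermal Imaging by Localization of Laser-Induced
    Temperature Peaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for photo-activated
    super-resolution thermography. A focused visible laser is raster-scanned
    over a sample on a sparse modulated lattice so that the induced
    temperature spots stay isolated; a far-infrared thermal camera records
    the evolving temperature field. The package simulates the full forward
    process (absorber maps, scan schedules, heat diffusion with Newton
    cooling, gray-body radiometry, camera sampling with NETD or photon shot
    noise), detects temperature peaks in per-pixel time traces, localizes
    each peak by two-step 2D Gaussian fitting to sub-pixel precision,
    renders the super-resolved map of absorptive centers, and quantifies
    resolution against the Rayleigh criterion and the Abbe diffraction
    limit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
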
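Package: ffoctsim
Title: Digital Twin of a Spectral-Shaping Swept Source for Full-Field OCT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates an acousto-optic tunable filter (AOTF) based
    spectral-shaping light source and the full-field optical coherence
    tomography (FFOCT) imaging chain it drives. Designs voltage/dwell
    schedules that synthesize arbitrary illumination spectra within one
    camera exposure (time-domain mode) and k-linear sweep plans with
    exposure-time shaping (swept-source mode); simulates phase-stepped
    interference signals and k-stacks on synthetic phantoms, including
    instantaneous-linewidth fringe washout and shot noise; reconstructs
    depth profiles by windowed k-space Fourier transform and measures
    point-spread-function metrics (FWHM, sidelobe level, roll-off, depth
    range); and performs spectroscopic particle analysis with an exact
    Mie backscattering series and principal-component spectral filtering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml,
    tiff,
    pracma,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
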
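---
title: "Spectral shaping for full-field OCT: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral shaping for full-field OCT: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffoctsim)
```

This vignette documents the signal models behind `ffoctsim`, the parameter
conventions and defaults, the design choices made where several reasonable
options existed, and what the synthetic tests do and do not establish about
real instruments.

## The source model

The tunable source is a supercontinuum laser filtered by an acousto-optic
tunable filter (AOTF). Three calibration curves, bundled in a
`calibration_table`, characterize it:

* **voltage → wavelength**: strictly monotone (decreasing on the shipped
  default, spanning 575–1040 nm over 0–10 V). Interpolation uses a
  monotone piecewise-cubic Hermite spline (Fritsch–Carlson): it passes
  exactly through the nodes and cannot overshoot, which guarantees an
  invertible map; the inverse is found by bracketed root finding and
  round-trips to better than $10^{-6}$ nm.
* **instantaneous linewidth**: the FWHM of the transmitted line, growing
  linearly from 2.5 nm (575 nm) to 9 nm (1040 nm) on the default table.
  The line *shape* is taken as Gaussian. The physical AOTF passband shape
  is device-specific; the Gaussian choice makes the coherence and roll-off
  closed forms available and is the only assumption the washout model
  rests on.
* **efficiency**: relative spectral irradiance at the sample, a smooth
  peak-normalized bump centered near 800 nm by default.

Derived source quantities: the temporal coherence length uses
$l_c = \lambda_0^2 / (2\Delta\lambda)$ (the conventional order-of-magnitude
definition; the Gaussian-envelope-FWHM alternative,
$(4\ln 2/\pi)\,\lambda_0^2/\Delta\lambda$, is available as a documented
option but is never the default). The multimode-fiber mode count uses the
step-index V-number convention $M = V^2/2$ per polarization with
$V = \pi d \,\mathrm{NA}/\lambda$; the wavelength is always an explicit
argument because a "maximum mode count" without a stated wavelength is
ambiguous — the shipped 200 µm / 0.39 NA fiber gives $4.16\times10^4$
modes at 850 nm.

Speckle from modal interference is modeled per pixel as the squared
magnitude of a sum of independent circular complex Gaussian mode
amplitudes (variance $1/n_\text{modes}$ each), i.e. fully developed
speckle: a single pattern has contrast 1 for any mode count, and averaging
$N$ independent patterns — the emulation of active mode mixing — reduces
the contrast as $1/\sqrt N$. A unit-amplitude-phasor model was considered
and rejected: with few phasors its single-pattern contrast is
$\sqrt{1 - 1/n}$, which contradicts the fully-developed limit the model is
meant to reproduce. No fiber propagation, polarization, or mode
correlation is simulated; the mode count enters the statistics only
through the Gaussian limit it justifies.

## Sequence design

**Time-domain shaping.** A target spectrum (rectangular, Gaussian,
Blackman, or tabulated) is synthesized by stepping the AOTF through
`n_steps` equally spaced wavelengths across the target support inside one
camera exposure, with dwell times
$\tau_i \propto S(\lambda_i)/\eta(\lambda_i)$ — the division by the source
efficiency $\eta$ makes the *detected* time-integrated spectrum match the
commanded one. Defaults: 64 steps per exposure and a 3 µs dwell quantum
(the AOTF crystal response time); dwells are quantized by
largest-remainder apportionment so their sum always equals the exposure to
within one quantum. Equal spacing with proportional dwell was preferred
over equal-probability quantile placement because the commanded waveform is
then a continuous voltage ramp with variable local slope, matching how the
hardware is driven; both satisfy the round-trip property.

Shape conventions: all parametric targets realize the *commanded* spectral
FWHM. The truncated Gaussian keeps a finite support of width FWHM/0.6
(cut at about $1.96\sigma$). The Blackman window (coefficients 0.42, 0.5,
0.08) has a half-maximum width of 0.40536 of its support, so its support is
FWHM/0.40536. An alternative sharing one support width across all three
shapes was rejected because it would make the realized Blackman FWHM 0.68
of the commanded value, defeating the point of an equal-FWHM comparison.

The predicted integrated spectrum is the dwell-weighted sum of the
instantaneous Gaussian lines, *without* deconvolving the line by default
(an optional Richardson–Lucy pre-compensation exists behind a flag). This
convolution sets a hard floor for sharp-edged targets: a step edge cannot
be synthesized more sharply than the line itself, so a rectangular target
with linewidth equal to a tenth of its FWHM carries an irreducible RMS
error of about 10% of peak concentrated at its edges, no matter how dwells
are chosen (verified against an optimal nonnegative least-squares design).
Smooth targets (Gaussian, Blackman, LED-like) round-trip to well under 5%
RMS under the same conditions.

The RF driver (50 µs) and acoustic propagation (3 µs) delays are constant;
`apply_timing_delays()` advances the command timeline by their sum exactly
once, so the optical output aligns with the exposure.

**Swept-source sweeps.** `design_k_linear_sweep()` places the per-frame
wavenumbers strictly uniformly between the band edges (the uniformity is
asserted by construction, not assumed downstream), and
`design_exposure_shaping()` sets the per-frame exposure weight to
$1/\eta(\lambda_n)$, normalized to a maximum of 1, so the product
$\eta\,w$ is constant to within floating-point rounding — the duty-cycle
equalization of the detected spectrum.

## Forward model and reconstruction

The interference model is scalar and linearized: for reflectors with
amplitude reflectivity $a_r = \sqrt{R_r}$ at optical path difference
$\Delta_r = 2 z_r n_\text{medium} - \Delta_\text{ref}$,

$$I_p = R_\text{ref} + \textstyle\sum_r a_r^2 +
\sum_r 2\sqrt{R_\text{ref}}\,a_r\,|\gamma(\Delta_r)|
\cos(\arg\gamma(\Delta_r) + \phi_p),$$

with $\gamma$ the normalized fringe envelope (Fourier transform of the
spectral density in $k$, trapezoid quadrature, $|\gamma(0)| = 1$). Mutual
interference between sample reflectors is deliberately omitted — the model
targets weakly reflecting samples, and the omission is what makes the
superposition property exact. As a consequence the modeled intensity can
go negative when fringe amplitudes exceed the DC level (strong reflectors
in phase); the simulator warns and clips in that regime, and tests stay
within the linear domain. OPD is always twice the geometric depth times
the medium index (double pass); depth axes are OPD/2.

Swept-source frames add two effects: the per-frame fringe visibility left
after washout by the instantaneous Gaussian line,
$V_n(\Delta) = \exp[-\delta k_n^2 \Delta^2/(16\ln 2)]$ with
$\delta k_n = 2\pi\,\delta\lambda_n/\lambda_n^2$ (this closed form is the
fringe envelope of the Gaussian line, cross-checked numerically), and
optional Poisson shot noise, scaled so the brightest noiseless frame fills
a configurable fraction (default 0.8) of the camera full well, then
clipped at the full well. Shot noise is the only noise source modeled; a
real source adds a small excess (the modeled instrument class reaches
about 1.2 times shot noise), which is not simulated.

Reconstruction follows the standard order of operations: subtract the
reference frames (incoherent background), divide out the declared exposure
weights and efficiency, multiply by the spectral window — Hamming
(0.54/0.46) by default — zero-pad (default factor 8; the factor is a
sampling refinement only and never changes peak positions by more than a
coarse bin), FFT along $k$, and keep the conjugate-free half. The depth
axis is $z_m = m\,2\pi/(N_\text{pad}\,\delta k)/2$.

Metrics: FWHM is measured on the *amplitude* profile by linear
interpolation of the half-maximum crossings (the quoted theoretical
resolution is the half width of a cardinal sine, measured the same way);
the peak sidelobe level is the highest local maximum outside the main lobe
(bounded by the first local minima), excluding the DC bin, with a floor
flag when no sidelobe emerges from numerical noise. The depth range of an
$N$-frame sweep is $(\pi/\delta k)/4$: the Nyquist OPD halved for the
depth convention and halved again for conjugate-free sample placement;
this convention is what reproduces the instrument-class figure of about
65 µm for 250 frames over 650–950 nm, and the single-sided alternative
(about 128 µm) sits behind a flag.

Two subtleties worth knowing. First, a spectrum that is rectangular *in
wavelength* is not rectangular in $k$ (Jacobian $\lambda^2/2\pi$), so its
axial response is about 1.5% wider than the ideal cardinal sine; the
"theoretical resolution" figures in this package always refer to the
k-flat (duty-cycle equalized) band, 1.242 µm FWHM for 650–950 nm. Second,
for *equal spectral FWHM* the three standard shapes do **not** give equal
axial main-lobe widths — the window-transform coefficients differ
(7.59/Δk for the rectangle, 6.12/Δk for the truncated Gaussian, 5.85/Δk
for Blackman, about 25% spread) — while the sidelobe ordering (roughly
−13, −31, −58 dB) is robust; the tests assert the honest ~25% agreement
band and the ≥10 dB-per-step sidelobe hierarchy.

## Spectroscopy

Constant-coherence-length families command Gaussian targets with
$\Delta\lambda_i = \lambda_i^2/(2 l_c)$; in $k$ all members then share the
same FWHM $\pi/l_c$, so the simulated axial widths agree to well under 1%
across 750–950 nm — the property that makes wavelength series comparable
without changing the probed volume.

The Mie backscattering efficiency is computed from the exact series with
logarithmic-derivative downward recurrence for $D_n(mx)$ and upward
Riccati–Bessel recurrence in $x$, truncated at
$n_\max = \lceil x + 4x^{1/3} + 2\rceil$,
$Q_\text{back} = x^{-2}\left|\sum_n (2n+1)(-1)^n(a_n - b_n)\right|^2$.
Only real indices are supported. The test oracle is an independent
Bohren–Huffman evaluation through half-integer Bessel functions; agreement
is at the $10^{-6}$ level for $x \in [0.1, 20]$ and the Rayleigh limit
$4x^4|(m^2-1)/(m^2+2)|^2$ is met within 1% for $x \le 0.05$. "Backscattering
coefficient" is interpreted as the efficiency $Q_\text{back}$; the
cross-section is available via a flag. Default indices are polystyrene
beads (1.59) in agar/water (1.34) — the bead material named by the
emulated experiment's methods; silica can be selected instead.

The synthetic bead experiment places beads of two diameters (990 and
505 nm) on a jittered grid (so a simple threshold/area blob segmenter —
deliberately simple, no learning — recovers each one), renders
diffraction-like Gaussian spots whose peak follows
$a_p\,Q_\text{back}(\lambda)$ on a 9-point 750–950 nm grid (25 nm steps;
an 11-point option exists because the emulated experiment's stated grid is
internally inconsistent), and contaminates 30% of beads with a colocated
aggregate contribution (5 µm effective sphere, weighted to the bead's mean
level by default) plus 5% additive noise. Per-particle spectra are the
maximum amplitude within each mask per wavelength. PCA filtering is
mean-centered (the uncentered variant is a flag) and keeps three
components; filtering is idempotent and the energy fractions are ordinary
variance fractions. Classification is nearest-template on unit-normalized
spectra. On the default phantom the aggregate contamination visibly
distorts the median raw spectrum while class assignment against the
injected Mie templates stays above 90% and the per-class medians of the
filtered spectra match the injected curves within 15% normalized RMS.

## Problem sizes and reproducibility

All simulations in the tests and the acceptance script run in A-line
(scalar) mode with spectral grids of 1200–4000 samples, OPD grids of a few
thousand points, 250-frame sweeps, and a 200-bead phantom on a
~360×360-pixel grid — sizes chosen so the whole suite completes in under a
minute on one core while keeping discretization errors one to two orders
below every tolerance asserted. Every stochastic operation takes an
explicit seed and is bitwise reproducible; `run_experiment()` writes the
seed, a config hash, and the package version into its manifest, and
reruns produce byte-identical CSV/JSON.

## What the synthetic tests do not show

The phantoms are idealized: discrete scalar reflectors without mutual
interference, no dispersion, no aberrations or spatial-coherence
cross-talk, no motion, no camera readout beyond full-well clipping and
Poisson noise, and speckle that is spatially white rather than correlated
at the diffraction scale. Passing tests therefore validate the signal
processing chain and the analytic performance envelope of the design —
not image quality on tissue. Measured figures that depend on unpublished
device details (the exact linewidth-versus-wavelength profile, PCA energy
fractions of a particular sample, sub-theoretical measured PSF widths) are
reproduced only conditionally on the documented model assumptions, or not
at all.
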
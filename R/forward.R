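#' Complex fringe envelope (coherence function) of a spectrum
#'
#' gamma(OPD) = integral of S(k) exp(i k OPD) dk, evaluated by trapezoidal
#' quadrature on the spectrum's wavenumber grid after normalizing S to unit
#' integrated power, so |gamma(0)| = 1. A rectangular spectrum of width
#' delta-k gives |gamma| = |sinc(delta_k * OPD / 2)|; a Gaussian spectrum of
#' FWHM delta-k gives a Gaussian envelope of OPD-FWHM `8 log(2) / delta_k`.
#'
#' @param spectrum an [spectrum_density()] (wavelength or wavenumber grid)
#' @param opd optical path differences, um (vectorized)
#' @return complex vector, same length as `opd`
#' @export
fringe_envelope <- function(spectrum, opd) {
  stopifnot(inherits(spectrum, "ffoct_spectrum"))
  sk <- as_wavenumber(spectrum)
  p <- spectrum_power(sk)
  if (p <= 0) stopf("spectrum has zero integrated power")
  k <- sk$grid
  s <- sk$density / p
  # trapezoidal weights
  w <- c(diff(k) / 2, 0) + c(0, diff(k) / 2)
  ph <- outer(k, opd * 1000)          # um -> nm
  as.vector(t(s * w) %*% exp(1i * ph))
}

#' Phase-stepped TD FFOCT frames for a phantom
#'
#' Scalar (A-line) signal model. For phase step p,
#' `I_p = I_dc + sum_r 2 sqrt(R_ref) a_r |gamma(D_r)| cos(arg gamma(D_r) + phi_p)`
#' with `D_r = 2 z_r n_medium - reference_opd` and
#' `I_dc = R_ref + sum_r a_r^2` (all single-arm intensities). In image mode,
#' `maps` supplies one per-pixel amplitude map per reflector and the
#' intensities are matrices.
#'
#' @param ph a [phantom()]
#' @param spectrum illumination spectrum, an `ffoct_spectrum`
#' @param reference_opd reference-arm OPD, um
#' @param phases phase steps, rad; length 4 (default `c(0, pi/2, pi, 3*pi/2)`)
#'   or 2 (`c(0, pi)`)
#' @param r_ref reference intensity reflectivity R_ref
#' @param maps optional list of per-reflector pixel maps (matrices) that
#'   multiply the reflector amplitude
#' @return a `phase_stepped_frames` object: list with `phases`, `intensities`
#'   (list, one scalar or matrix per phase) and `reference_reflectivity`
#' @export
td_frames <- function(ph, spectrum, reference_opd = 0,
                      phases = c(0, pi / 2, pi, 3 * pi / 2), r_ref = 1,
                      maps = NULL) {
  stopifnot(inherits(ph, "phantom"))
  if (!length(phases) %in% c(2L, 4L))
    stopf("2 or 4 phase steps are supported")
  amp <- ph$reflectivity
  g <- if (length(ph$depth))
    fringe_envelope(spectrum, phantom_opd(ph) - reference_opd) else complex(0)
  if (is.null(maps)) {
    dc <- r_ref + sum(amp^2)
    intens <- lapply(phases, function(phi) {
      dc + sum(2 * sqrt(r_ref) * amp * Mod(g) * cos(Arg(g) + phi))
    })
  } else {
    stopifnot(length(maps) == length(amp))
    dc <- r_ref + Reduce(`+`, lapply(seq_along(amp),
                                     function(r) (amp[r] * maps[[r]])^2))
    intens <- lapply(phases, function(phi) {
      ac <- Reduce(`+`, lapply(seq_along(amp), function(r) {
        2 * sqrt(r_ref) * amp[r] * maps[[r]] * Mod(g[r]) * cos(Arg(g[r]) + phi)
      }))
      dc + ac
    })
  }
  structure(list(phases = phases, intensities = intens,
                 reference_reflectivity = r_ref),
            class = "phase_stepped_frames")
}

#' Simulate a TD FFOCT axial scan of the reference arm
#'
#' At each reference OPD the four (or two) phase-stepped frames are formed
#' with [td_frames()] and demodulated with [demodulate_phases()]; for a unit
#' mirror the demodulated amplitude equals `2 sqrt(R_ref) |gamma|`, i.e. the
#' fringe envelope of the spectrum.
#'
#' @param ph a [phantom()]
#' @param spectrum illumination spectrum
#' @param opd_grid reference OPDs to scan, um (ascending, uniform)
#' @param phases phase steps (see [td_frames()])
#' @param r_ref reference reflectivity
#' @return an [axial_profile()] on the depth grid `opd_grid / 2`
#' @export
simulate_axial_scan <- function(ph, spectrum, opd_grid,
                                phases = c(0, pi / 2, pi, 3 * pi / 2),
                                r_ref = 1) {
  amp <- vapply(opd_grid, function(d) {
    demodulate_phases(td_frames(ph, spectrum, d, phases, r_ref))
  }, numeric(1))
  axial_profile(opd_grid / 2, amp,
                meta = list(mode = "td", window = "none", zero_pad = 1))
}

#' Swept-source interferogram stack
#'
#' Container for a simulated (or loaded) SS FFOCT acquisition: one intensity
#' per frame of the sweep plan (scalar mode) or one image per frame (3-D
#' array with the frame index last), plus the matching reference frames
#' recorded with the object arm blocked.
#'
#' @param plan a [sweep_plan()]
#' @param frames numeric vector (length = frames) or array (H x W x frames)
#' @param reference_frames same shape as `frames`
#' @param meta named list of provenance
#' @return a `kstack` object
#' @export
kstack <- function(plan, frames, reference_frames, meta = list()) {
  stopifnot(inherits(plan, "sweep_plan"))
  n <- length(plan$wavelengths)
  nf <- if (is.array(frames) && length(dim(frames)) == 3) dim(frames)[3]
        else length(frames)
  if (nf != n) stopf("frames count (%d) must equal plan length (%d)", nf, n)
  if (any(frames < 0) || any(reference_frames < 0))
    stopf("intensities must be >= 0")
  structure(list(plan = plan, frames = frames,
                 reference_frames = reference_frames, meta = meta),
            class = "kstack")
}

#' @export
print.kstack <- function(x, ...) {
  cat(sprintf("<kstack> %d frames, %.5g-%.5g nm%s\n",
              length(x$plan$wavelengths), min(x$plan$wavelengths),
              max(x$plan$wavelengths),
              if (is.array(x$frames)) sprintf(", %d x %d px",
                                              dim(x$frames)[1], dim(x$frames)[2])
              else " (A-line mode)"))
  invisible(x)
}

# Gaussian fringe-washout visibility of an instantaneous line of FWHM `lw`
# (nm) at center `lam` (nm), for an OPD in um.
line_visibility <- function(lam, lw, opd_um) {
  dk <- 2 * pi * lw / lam^2            # line FWHM in k, rad/nm
  exp(-dk^2 * (opd_um * 1000)^2 / (16 * log(2)))
}

#' Simulate a swept-source FFOCT k-stack (A-line mode)
#'
#' Frame n of the sweep plan records
#' `w_n eta_n (DC + sum_r 2 sqrt(R_ref) a_r V_n(D_r) cos(k_n D_r))`
#' where `V_n` is the fringe visibility left after washout by the
#' instantaneous Gaussian line at that frame's wavelength (closed form,
#' consistent with [fringe_envelope()] of the line). The reference frames
#' contain the same signal with the interference term removed. Optional
#' Poisson shot noise: the brightest noiseless frame is mapped to
#' `fill * full_well` electrons, sampled, clipped at `full_well` and mapped
#' back; `fill > 1` warns about saturation.
#'
#' @param ph a [phantom()]
#' @param plan a [sweep_plan()]
#' @param table a [calibration_table()]
#' @param r_ref reference reflectivity
#' @param full_well camera full-well capacity, electrons; `NULL` (default)
#'   disables shot noise
#' @param fill fraction of the full well reached by the brightest frame
#' @param seed RNG seed for the shot noise
#' @return a [kstack()]
#' @export
simulate_ss_stack <- function(ph, plan, table, r_ref = 1, full_well = NULL,
                              fill = 0.8, seed = 1) {
  stopifnot(inherits(ph, "phantom"), inherits(plan, "sweep_plan"),
            inherits(table, "calibration_table"))
  lam <- plan$wavelengths
  check_in_range(lam, calibration_wavelength_range(table), "wavelength")
  lw <- linewidth_at(table, lam)
  eta <- efficiency_at(table, lam)
  w <- plan$exposure_weights
  opd <- phantom_opd(ph)
  dc <- r_ref + sum(ph$reflectivity^2)
  ac <- rep(0, length(lam))
  for (r in seq_along(opd)) {
    vis <- line_visibility(lam, lw, opd[r])
    ac <- ac + 2 * sqrt(r_ref) * ph$reflectivity[r] * vis *
      cos(plan$wavenumbers * opd[r] * 1000)
  }
  if (any(dc + ac < 0))
    warnf(paste0("fringe amplitude exceeds the DC level (linearized model ",
                 "without mutual interference terms); clipping at zero"))
  frames <- w * eta * (dc + ac)
  ref <- w * eta * dc
  meta <- list(noise = !is.null(full_well), seed = seed, eta = eta)
  if (!is.null(full_well)) {
    if (fill > 1) warnf("mean signal exceeds the full well; frames saturate")
    scale <- fill * full_well / max(frames)
    set.seed(seed)
    el <- stats::rpois(length(frames), frames * scale)
    frames <- pmin(el, full_well) / scale
    meta$full_well <- full_well
  }
  kstack(plan, pmax(frames, 0), pmax(ref, 0), meta = meta)
}
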
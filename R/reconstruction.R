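#' Reconstructed axial amplitude profile
#'
#' @param depth_grid ascending, uniform depth samples, um (depth = OPD/2)
#' @param amplitude non-negative amplitudes
#' @param meta named list (window name, zero-pad factor, mode, ...)
#' @return an `axial_profile` object
#' @export
axial_profile <- function(depth_grid, amplitude, meta = list()) {
  assert_num(depth_grid, "depth_grid")
  assert_num(amplitude, "amplitude", len = length(depth_grid), nonneg = TRUE)
  if (any(diff(depth_grid) <= 0)) stopf("`depth_grid` must be ascending")
  structure(list(depth_grid = depth_grid, amplitude = amplitude, meta = meta),
            class = "axial_profile")
}

#' @export
print.axial_profile <- function(x, ...) {
  pk <- which.max(x$amplitude)
  cat(sprintf("<axial_profile> %d samples, depth %.4g-%.4g um, peak at %.4g um\n",
              length(x$depth_grid), min(x$depth_grid), max(x$depth_grid),
              x$depth_grid[pk]))
  invisible(x)
}

#' @export
plot.axial_profile <- function(x, db = FALSE, ...) {
  y <- x$amplitude / max(x$amplitude)
  if (db) y <- 20 * log10(pmax(y, 1e-12))
  graphics::plot(x$depth_grid, y, type = "l", xlab = "depth (um)",
                 ylab = if (db) "amplitude (dB)" else "amplitude", ...)
  invisible(x)
}

#' Phase-stepped demodulation
#'
#' Four steps at \{0, pi/2, pi, 3 pi/2\}:
#' `A = 0.5 * sqrt((I_0 - I_pi)^2 + (I_pi/2 - I_3pi/2)^2)`;
#' two steps at \{0, pi\}: `A = |I_0 - I_pi| / 2`. Recovers the fringe
#' amplitude `2 sqrt(R_ref R_s) |gamma|` exactly in the noiseless model,
#' independent of the interferometric phase offset (4-phase case).
#'
#' @param frames a `phase_stepped_frames` object from [td_frames()]
#' @return demodulated amplitude (scalar or matrix, matching the frames)
#' @export
demodulate_phases <- function(frames) {
  stopifnot(inherits(frames, "phase_stepped_frames"))
  ph <- frames$phases
  ii <- frames$intensities
  if (length(ph) == 4L) {
    if (max(abs(ph - c(0, pi / 2, pi, 3 * pi / 2))) > 1e-9)
      stopf("4-phase demodulation expects phases 0, pi/2, pi, 3pi/2")
    0.5 * sqrt((ii[[1]] - ii[[3]])^2 + (ii[[2]] - ii[[4]])^2)
  } else if (length(ph) == 2L) {
    if (max(abs(ph - c(0, pi))) > 1e-9)
      stopf("2-phase demodulation expects phases 0, pi")
    abs(ii[[1]] - ii[[2]]) / 2
  } else stopf("2 or 4 phases required")
}

window_vector <- function(name, n) {
  x <- seq(0, 1, length.out = n)
  switch(name,
    none = rep(1, n),
    hamming = 0.54 - 0.46 * cos(2 * pi * x),
    hann = 0.5 - 0.5 * cos(2 * pi * x),
    blackman = 0.42 - 0.5 * cos(2 * pi * x) + 0.08 * cos(4 * pi * x),
    stopf("unknown window '%s'", name))
}

#' Swept-source depth reconstruction (reference subtraction, window, k-FFT)
#'
#' Subtracts the reference frames (incoherent light), divides out the
#' declared exposure weights and source efficiency, applies a spectral
#' window (Hamming by default, coefficients 0.54/0.46), zero-pads to
#' `zero_pad * N` samples and Fourier-transforms along k. The depth axis is
#' `z_m = m * 2 pi / (N_pad * delta_k) / 2` (depth = OPD/2); only the
#' conjugate-free half up to the Nyquist OPD is returned.
#'
#' @param stack a [kstack()] (A-line mode: numeric frames; image mode:
#'   H x W x N array)
#' @param window `"hamming"` (default), `"hann"`, `"blackman"` or `"none"`
#' @param zero_pad integer zero-padding factor >= 1 (default 8)
#' @param flatten divide out declared exposure weights / efficiency before
#'   windowing (default TRUE)
#' @return A-line mode: an [axial_profile()] whose `meta` carries the
#'   windowed k-signal and the full complex transform. Image mode: a list
#'   with `volume` (complex H x W x depth array), `depth_grid` and `meta`.
#' @export
ss_reconstruct <- function(stack, window = "hamming", zero_pad = 8,
                           flatten = TRUE) {
  stopifnot(inherits(stack, "kstack"))
  if (zero_pad < 1) stopf("`zero_pad` must be >= 1")
  k <- stack$plan$wavenumbers
  dk <- diff(k)
  if (max(abs(dk - mean(dk))) / mean(dk) > 1e-9)
    stopf("k grid is not uniform; reconstruction requires a k-linear sweep")
  dk <- mean(dk)
  n <- length(k)
  if (is.null(stack$reference_frames))
    warnf("no reference frames; the DC term will dominate the transform")
  gain <- rep(1, n)
  if (flatten) {
    gain <- stack$plan$exposure_weights
    if (!is.null(stack$meta$eta)) gain <- gain * stack$meta$eta
  }
  w <- window_vector(window, n)
  npad <- as.integer(round(zero_pad * n))
  nz <- floor(npad / 2) + 1L
  depth <- (seq_len(nz) - 1L) * 2 * pi / (npad * dk) / 2 / 1000  # um
  if (is.array(stack$frames) && length(dim(stack$frames)) == 3) {
    d <- dim(stack$frames)
    sig <- matrix(stack$frames - stack$reference_frames, d[1] * d[2], d[3])
    sig <- sweep(sig, 2, gain, "/")
    sig <- sweep(sig, 2, w, "*")
    sig <- cbind(sig, matrix(0, nrow(sig), npad - n))
    tr <- t(stats::mvfft(t(sig)))
    vol <- array(tr[, seq_len(nz)], c(d[1], d[2], nz))
    return(list(volume = vol, depth_grid = depth,
                meta = list(window = window, zero_pad = zero_pad, dk = dk)))
  }
  sig <- (stack$frames - stack$reference_frames) / gain * w
  tr <- stats::fft(c(sig, rep(0, npad - n)))
  axial_profile(depth, Mod(tr[seq_len(nz)]),
                meta = list(mode = "ss", window = window, zero_pad = zero_pad,
                            dk = dk, windowed_signal = sig, full_fft = tr))
}

#' Full width at half maximum of an axial profile
#'
#' Linear-interpolated half-maximum crossing width of the *amplitude*
#' profile. Errors when the peak sits at the grid edge.
#'
#' @param profile an [axial_profile()]
#' @return FWHM in um
#' @export
fwhm <- function(profile) {
  stopifnot(inherits(profile, "axial_profile"))
  half_max_width(profile$depth_grid, profile$amplitude)
}

#' Peak sidelobe level of an axial profile
#'
#' `20 log10` of the highest local maximum outside the main lobe relative to
#' the main peak. The main lobe is bounded by the first local minima on each
#' side of the peak; the DC bin is excluded from the search. When no
#' sidelobe rises above the numerical floor the floor value is returned with
#' attribute `floor = TRUE`.
#'
#' @param profile an [axial_profile()]
#' @param floor_db numerical floor, dB (default -200)
#' @return sidelobe level in dB (<= 0), possibly with attribute `floor`
#' @export
peak_sidelobe_db <- function(profile, floor_db = -200) {
  stopifnot(inherits(profile, "axial_profile"))
  y <- profile$amplitude / max(profile$amplitude)
  n <- length(y)
  skip_dc <- identical(profile$meta$mode, "ss")
  i0 <- which.max(y)
  ir <- i0; while (ir < n && y[ir + 1] <= y[ir]) ir <- ir + 1L
  il <- i0; while (il > 1 && y[il - 1] <= y[il]) il <- il - 1L
  outside <- setdiff(seq_len(n), il:ir)
  if (skip_dc) outside <- setdiff(outside, 1L)
  # local maxima outside the main lobe
  cand <- outside[vapply(outside, function(i) {
    (i == 1 || y[i] >= y[i - 1]) && (i == n || y[i] >= y[i + 1])
  }, logical(1))]
  lv <- if (length(cand)) max(y[cand]) else 0
  if (lv <= 10^(floor_db / 20))
    return(structure(floor_db, floor = TRUE))
  20 * log10(lv)
}

#' Summary PSF metrics of an axial profile
#' @param profile an [axial_profile()]
#' @return list with `peak_depth` (um), `fwhm` (um), `peak_sidelobe_db` (dB)
#' @export
psf_metrics <- function(profile) {
  stopifnot(inherits(profile, "axial_profile"))
  list(peak_depth = profile$depth_grid[which.max(profile$amplitude)],
       fwhm = fwhm(profile),
       peak_sidelobe_db = as.numeric(peak_sidelobe_db(profile)))
}

#' Sensitivity roll-off curve
#'
#' For each requested OPD, simulates a mirror at that optical path, runs the
#' swept-source reconstruction and records the peak amplitude in dB relative
#' to the smallest OPD. The decay is caused by fringe washout from the
#' finite instantaneous linewidth and is monotone for Gaussian lines.
#'
#' @param opds mirror optical paths, um
#' @param plan a [sweep_plan()]
#' @param table a [calibration_table()]
#' @param window,zero_pad reconstruction settings
#' @return data.frame with columns `opd_um` and `peak_db`
#' @export
rolloff_curve <- function(opds, plan, table, window = "none", zero_pad = 4) {
  stopifnot(inherits(plan, "sweep_plan"))
  max_opd <- pi / plan_dk(plan) / 1000   # Nyquist OPD, um
  if (any(opds > max_opd))
    stopf("OPD %.4g um beyond the Nyquist optical path (%.4g um)",
          max(opds), max_opd)
  dz <- 2 * pi / (zero_pad * length(plan$wavenumbers) * plan_dk(plan)) / 2 / 1000
  peak <- vapply(opds, function(d) {
    st <- simulate_ss_stack(phantom(d / 2), plan, table)
    pr <- ss_reconstruct(st, window = window, zero_pad = zero_pad)
    max(pr$amplitude[pr$depth_grid > 2 * dz])
  }, numeric(1))
  data.frame(opd_um = opds, peak_db = 20 * log10(peak / peak[which.min(opds)]))
}

#' Conjugate-free depth range of a k-linear sweep
#'
#' With N frames over the band, the k step is
#' `delta_k = (2 pi / lam_min - 2 pi / lam_max) / (N - 1)` and the Nyquist
#' OPD is `pi / delta_k`. The returned range halves this once for the
#' depth = OPD/2 convention and once more for conjugate-free placement of
#' the sample surface near zero OPD (`conjugate_free = FALSE` skips the
#' second halving).
#'
#' @param n_frames number of frames (>= 2)
#' @param lam_min,lam_max band edges, nm
#' @param conjugate_free halve the range for conjugate-free placement
#'   (default TRUE)
#' @return depth range, um
#' @examples
#' depth_range(250, 650, 950)  # about 64 um
#' @export
depth_range <- function(n_frames, lam_min, lam_max, conjugate_free = TRUE) {
  if (n_frames < 2) stopf("n_frames must be >= 2")
  dk <- (2 * pi / lam_min - 2 * pi / lam_max) / (n_frames - 1)
  r <- (pi / dk) / 2 / 1000
  if (conjugate_free) r <- r / 2
  r
}

#' Export an axial profile as CSV
#' @param profile an [axial_profile()]
#' @param path CSV path
#' @return `path`, invisibly
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "axial_profile"))
  utils::write.csv(data.frame(depth_um = profile$depth_grid,
                              amplitude = profile$amplitude),
                   path, row.names = FALSE)
  invisible(path)
}
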
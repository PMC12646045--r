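#' Swept-source sweep plan
#'
#' One constant wavelength per camera frame, uniformly spaced in wavenumber
#' k = 2*pi/lambda, with per-frame exposure weights (duty-cycle shaping).
#' Frames are ordered by ascending k (descending wavelength).
#'
#' @param wavelengths per-frame center wavelengths, nm
#' @param exposure_weights per-frame relative exposure times, > 0
#' @param frame_period camera frame period, us
#' @return a `sweep_plan` with fields `wavelengths`, `wavenumbers` (rad/nm),
#'   `exposure_weights`, `frame_period`
#' @export
sweep_plan <- function(wavelengths, exposure_weights = rep(1, length(wavelengths)),
                       frame_period = 1e4) {
  assert_num(wavelengths, "wavelengths", positive = TRUE)
  assert_num(exposure_weights, "exposure_weights", len = length(wavelengths),
             positive = TRUE)
  k <- 2 * pi / wavelengths
  if (any(diff(k) <= 0))
    stopf("wavelengths must be strictly descending (ascending in k)")
  dk <- diff(k)
  if (length(dk) > 1 && max(abs(dk - mean(dk))) / mean(dk) > 1e-9)
    stopf("wavenumbers are not uniformly spaced (max relative deviation %.3g)",
          max(abs(dk - mean(dk))) / mean(dk))
  structure(list(wavelengths = wavelengths, wavenumbers = k,
                 exposure_weights = exposure_weights,
                 frame_period = frame_period),
            class = "sweep_plan")
}

#' @export
print.sweep_plan <- function(x, ...) {
  cat(sprintf("<sweep_plan> %d frames, %.5g-%.5g nm, weights in [%.3g, %.3g]\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              min(x$exposure_weights), max(x$exposure_weights)))
  invisible(x)
}

#' k spacing of a sweep plan
#' @param plan a `sweep_plan`
#' @return scalar delta-k, rad/nm
#' @export
plan_dk <- function(plan) {
  stopifnot(inherits(plan, "sweep_plan"))
  mean(diff(plan$wavenumbers))
}

#' Design a k-linear sweep
#'
#' Wavenumbers `k_n` uniformly spaced between `2*pi/lam_max` and
#' `2*pi/lam_min` inclusive; the per-frame wavelengths are `2*pi/k_n`. All
#' wavelengths must be resolvable through the calibration when a table is
#' given.
#'
#' @param lam_min,lam_max band edges, nm
#' @param n_frames number of frames (>= 2)
#' @param table optional [calibration_table()] used to validate the band
#' @param frame_period camera frame period, us
#' @return a `sweep_plan`
#' @examples
#' design_k_linear_sweep(650, 950, 3)$wavelengths  # middle = harmonic mean
#' @export
design_k_linear_sweep <- function(lam_min, lam_max, n_frames, table = NULL,
                                  frame_period = 1e4) {
  assert_num(lam_min, "lam_min", len = 1, positive = TRUE)
  assert_num(lam_max, "lam_max", len = 1, positive = TRUE)
  if (lam_min >= lam_max) stopf("lam_min must be < lam_max")
  if (n_frames < 2) stopf("n_frames must be >= 2")
  if (!is.null(table)) {
    rng <- calibration_wavelength_range(table)
    if (lam_min < rng[1] || lam_max > rng[2])
      stopf("band [%g, %g] nm outside the calibrated range [%.5g, %.5g] nm",
            lam_min, lam_max, rng[1], rng[2])
  }
  k <- seq(2 * pi / lam_max, 2 * pi / lam_min, length.out = n_frames)
  sweep_plan(2 * pi / k, frame_period = frame_period)
}

#' Duty-cycle exposure shaping that flattens the detected spectrum
#'
#' Sets the per-frame exposure weight proportional to the reciprocal of the
#' source efficiency at that frame's wavelength, normalized so the largest
#' weight is 1. The product efficiency x weight is then constant across the
#' sweep, equalizing the detected spectrum over the full band.
#'
#' @param plan a `sweep_plan`
#' @param table a [calibration_table()] (or a function lambda -> efficiency)
#' @return the plan with updated `exposure_weights`
#' @export
design_exposure_shaping <- function(plan, table) {
  stopifnot(inherits(plan, "sweep_plan"))
  eta <- if (is.function(table)) table(plan$wavelengths)
         else efficiency_at(table, plan$wavelengths)
  if (any(eta <= 0))
    stopf("source efficiency is zero at %.5g nm; cannot flatten",
          plan$wavelengths[which(eta <= 0)[1]])
  w <- 1 / eta
  plan$exposure_weights <- w / max(w)
  plan
}

#' Export a sweep plan as CSV
#'
#' Columns: `frame,wavelength_nm,wavenumber_rad_per_nm,exposure_weight`
#' (plus `voltage_V` when a calibration is supplied).
#'
#' @param plan a `sweep_plan`
#' @param path CSV path
#' @param table optional [calibration_table()] to add commanded voltages
#' @return `path`, invisibly
#' @export
write_sweep_csv <- function(plan, path, table = NULL) {
  stopifnot(inherits(plan, "sweep_plan"))
  d <- data.frame(frame = seq_along(plan$wavelengths),
                  wavelength_nm = plan$wavelengths,
                  wavenumber_rad_per_nm = plan$wavenumbers,
                  exposure_weight = plan$exposure_weights)
  if (!is.null(table)) d$voltage_V <- voltage_for_wavelength(table, d$wavelength_nm)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
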
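#' Timed AOTF voltage schedule for one camera exposure
#'
#' A time-domain spectral-shaping schedule: an ordered list of
#' (voltage, dwell) steps executed within one exposure. Dwells are quantized
#' to the AOTF crystal response time (3 us by default) and sum to the
#' exposure within one quantum. The RF driver and the acoustic propagation
#' add constant command delays which [apply_timing_delays()] compensates.
#'
#' @param steps data.frame with columns `voltage_V`, `wavelength_nm`,
#'   `dwell_us` (and optionally `t_start_us`, the optical start time of each
#'   step within the exposure)
#' @param exposure camera exposure time, us
#' @param rf_delay constant RF-driver delay, us (default 50)
#' @param acoustic_delay ultrasound propagation delay, us (default 3)
#' @param min_dwell dwell quantum, us (default 3)
#' @return a `voltage_sequence` object
#' @export
voltage_sequence <- function(steps, exposure, rf_delay = 50, acoustic_delay = 3,
                             min_dwell = 3) {
  stopifnot(is.data.frame(steps))
  need <- c("voltage_V", "wavelength_nm", "dwell_us")
  if (!all(need %in% names(steps)))
    stopf("`steps` needs columns %s", paste(need, collapse = ", "))
  assert_num(steps$dwell_us, "dwell_us", nonneg = TRUE)
  if (any(steps$dwell_us < min_dwell))
    stopf("all dwells must be >= the %g us quantum", min_dwell)
  if (abs(sum(steps$dwell_us) - exposure) > min_dwell)
    stopf("total dwell (%g us) must equal the exposure (%g us) within one quantum",
          sum(steps$dwell_us), exposure)
  if (is.null(steps$t_start_us))
    steps$t_start_us <- cumsum(steps$dwell_us) - steps$dwell_us
  structure(list(steps = steps, exposure = exposure, rf_delay = rf_delay,
                 acoustic_delay = acoustic_delay, min_dwell = min_dwell,
                 delays_applied = FALSE),
            class = "voltage_sequence")
}

#' @export
print.voltage_sequence <- function(x, ...) {
  cat(sprintf("<voltage_sequence> %d steps, exposure %g us, %g-%g nm%s\n",
              nrow(x$steps), x$exposure, min(x$steps$wavelength_nm),
              max(x$steps$wavelength_nm),
              if (isTRUE(x$delays_applied)) ", delays compensated" else ""))
  invisible(x)
}

# Round dwells to multiples of `quantum` while preserving their total
# (largest-remainder apportionment).
quantize_dwells <- function(dwell, quantum, total) {
  n_quanta <- round(total / quantum)
  raw <- dwell / sum(dwell) * n_quanta
  base <- floor(raw)
  rem <- n_quanta - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base * quantum
}

#' Design a time-domain spectral-shaping schedule
#'
#' Places `n_steps` equally spaced wavelengths across the target support and
#' assigns each a dwell proportional to the target density divided by the
#' source efficiency (so the *detected* time-integrated spectrum matches the
#' target), renormalized to the exposure and quantized to the dwell quantum.
#' Steps are emitted in monotone wavelength order. Steps whose quantized
#' dwell is zero are dropped.
#'
#' An optional Richardson-Lucy pre-compensation of the target by the
#' instantaneous line (off by default; the integrated spectrum is otherwise
#' predicted without deconvolving the line) can sharpen tabulated structure
#' broader than the linewidth, but cannot synthesize features below it.
#'
#' @param target a [target_spectrum()]
#' @param table a [calibration_table()]
#' @param exposure camera exposure, us
#' @param n_steps number of discrete wavelengths (default 64)
#' @param min_dwell dwell quantum, us (default 3)
#' @param compensate_linewidth logical; Richardson-Lucy pre-compensation flag
#' @param rl_iterations Richardson-Lucy iteration count
#' @return a `voltage_sequence`
#' @examples
#' tab <- default_calibration()
#' sq <- design_td_sequence(target_spectrum("gaussian", 800, 60), tab, 9600)
#' @export
design_td_sequence <- function(target, table, exposure, n_steps = 64,
                               min_dwell = 3, compensate_linewidth = FALSE,
                               rl_iterations = 20) {
  stopifnot(inherits(target, "target_spectrum"),
            inherits(table, "calibration_table"))
  if (n_steps * min_dwell > exposure)
    stopf("n_steps * min_dwell exceeds the exposure")
  sup <- target_support(target)
  rng <- calibration_wavelength_range(table)
  if (sup[1] < rng[1] || sup[2] > rng[2])
    stopf("target support [%.5g, %.5g] nm outside the calibrated range [%.5g, %.5g] nm",
          sup[1], sup[2], rng[1], rng[2])
  lam <- seq(sup[1], sup[2], length.out = n_steps)
  dens <- sample_target(target, lam)$density
  eta <- efficiency_at(table, lam)
  active <- dens > 0
  if (any(active & eta <= 0))
    stopf("source efficiency is zero inside the target support near %.5g nm",
          lam[which(active & eta <= 0)[1]])
  if (!is.null(target$fwhm)) {
    lw0 <- linewidth_at(table, target$center)
    if (target$fwhm < lw0)
      warnf("target FWHM (%.3g nm) below the instantaneous linewidth (%.3g nm); shaping cannot narrow the line",
            target$fwhm, lw0)
  }
  if (compensate_linewidth)
    dens <- richardson_lucy_1d(dens, lam, linewidth_at(table, lam),
                               rl_iterations)
  w <- ifelse(active, dens / eta, 0)
  dwell <- quantize_dwells(w, min_dwell, exposure)
  keep <- dwell > 0
  steps <- data.frame(voltage_V = voltage_for_wavelength(table, lam[keep]),
                      wavelength_nm = lam[keep], dwell_us = dwell[keep])
  steps <- steps[order(steps$wavelength_nm), , drop = FALSE]
  rownames(steps) <- NULL
  voltage_sequence(steps, exposure, min_dwell = min_dwell)
}

# Richardson-Lucy deconvolution of a sampled target by a Gaussian kernel of
# (possibly wavelength-dependent) FWHM, on a uniform grid.
richardson_lucy_1d <- function(dens, lam, fwhm, iterations) {
  sig <- fwhm / GAUSS_FWHM
  kmat <- outer(lam, seq_along(lam),
                function(l, j) exp(-(l - lam[j])^2 / (2 * sig[j]^2)))
  kmat <- sweep(kmat, 2, colSums(kmat), "/")
  est <- pmax(dens, 1e-12)
  for (i in seq_len(iterations)) {
    pred <- as.vector(kmat %*% est)
    ratio <- ifelse(pred > 0, dens / pred, 0)
    est <- est * as.vector(crossprod(kmat, ratio))
  }
  est / max(est)
}

#' Predict the time-integrated spectrum of a schedule
#'
#' Sums `dwell_i * instantaneous_spectrum(lambda_i)` over the steps; this is
#' what a spectrometer integrating over one exposure would record. The result
#' is normalized to unit peak.
#'
#' @param seq a `voltage_sequence`
#' @param table a [calibration_table()]
#' @param grid wavelength samples, nm
#' @return an `ffoct_spectrum`
#' @export
predict_integrated_spectrum <- function(seq, table, grid) {
  stopifnot(inherits(seq, "voltage_sequence"),
            inherits(table, "calibration_table"))
  lam <- seq$steps$wavelength_nm
  fw <- linewidth_at(table, lam)
  eff <- efficiency_at(table, lam)
  sig <- fw / GAUSS_FWHM
  m <- outer(grid, seq_along(lam),
             function(g, i) exp(-(g - lam[i])^2 / (2 * sig[i]^2)))
  dens <- as.vector(m %*% (seq$steps$dwell_us * eff))
  if (max(dens) > 0) dens <- dens / max(dens)
  spectrum_density(grid, dens, kind = "wavelength")
}

#' Compensate constant command delays
#'
#' The RF driver responds with a constant delay and the acoustic wave needs a
#' constant propagation time; the emitted command timeline is therefore
#' advanced by their sum so the optical output aligns with the camera
#' exposure. Idempotent: the shift is applied once.
#'
#' @param seq a `voltage_sequence`
#' @return the sequence with a `t_command_us` column
#'   (`t_start_us - rf_delay - acoustic_delay`)
#' @export
apply_timing_delays <- function(seq) {
  stopifnot(inherits(seq, "voltage_sequence"))
  if (isTRUE(seq$delays_applied)) return(seq)
  seq$steps$t_command_us <-
    seq$steps$t_start_us - seq$rf_delay - seq$acoustic_delay
  seq$delays_applied <- TRUE
  seq
}

#' Export a voltage schedule as CSV plus JSON sidecar
#'
#' CSV columns: `t_start_us,voltage_V,wavelength_nm,dwell_us` (plus
#' `t_command_us` when delays were applied); the sidecar records exposure,
#' delays and quantum.
#'
#' @param seq a `voltage_sequence`
#' @param path CSV path; the sidecar is written next to it as `<path>.json`
#' @return `path`, invisibly
#' @export
write_sequence_csv <- function(seq, path) {
  stopifnot(inherits(seq, "voltage_sequence"))
  cols <- intersect(c("t_start_us", "voltage_V", "wavelength_nm", "dwell_us",
                      "t_command_us"), names(seq$steps))
  utils::write.csv(seq$steps[, cols], path, row.names = FALSE)
  side <- list(exposure_us = seq$exposure, rf_delay_us = seq$rf_delay,
               acoustic_delay_us = seq$acoustic_delay,
               min_dwell_us = seq$min_dwell,
               delays_applied = isTRUE(seq$delays_applied))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
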
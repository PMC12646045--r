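#' AOTF voltage/wavelength calibration table
#'
#' Links the analog control voltage of the acousto-optic tunable filter to the
#' center wavelength of the transmitted line, together with the
#' wavelength-dependent instantaneous linewidth (FWHM) and relative source
#' efficiency (peak-normalized spectral irradiance at the sample plane).
#'
#' The voltage-to-wavelength relation is interpolated with a monotone
#' piecewise-cubic Hermite spline (Fritsch-Carlson), which passes exactly
#' through the nodes and cannot overshoot, so the mapping stays strictly
#' monotone and invertible. Linewidth and efficiency use linear interpolation.
#'
#' @param voltage ascending control voltages, V (>= 2 nodes)
#' @param wavelength center wavelengths at the nodes, nm; strictly monotone in
#'   voltage (either sign)
#' @param linewidth instantaneous FWHM at the nodes, nm, > 0
#' @param efficiency relative spectral irradiance at the nodes, >= 0
#' @return a `calibration_table` object
#' @examples
#' tab <- default_calibration()
#' wavelength_for_voltage(tab, 5)
#' @export
calibration_table <- function(voltage, wavelength, linewidth, efficiency) {
  n <- length(voltage)
  if (n < 2L) stopf("calibration needs at least 2 nodes")
  assert_num(voltage, "voltage", len = n)
  assert_num(wavelength, "wavelength", len = n, positive = TRUE)
  assert_num(linewidth, "linewidth", len = n, positive = TRUE)
  assert_num(efficiency, "efficiency", len = n, nonneg = TRUE)
  if (any(diff(voltage) <= 0)) stopf("`voltage` must be strictly ascending")
  if (!is_strictly_monotone(wavelength))
    stopf("`wavelength` must be strictly monotone in voltage")
  structure(list(voltage = voltage, wavelength = wavelength,
                 linewidth = linewidth, efficiency = efficiency),
            class = "calibration_table")
}

#' @export
print.calibration_table <- function(x, ...) {
  cat(sprintf(paste0("<calibration_table> %d nodes, %.4g-%.4g V -> %.5g-%.5g nm,",
                     " linewidth %.3g-%.3g nm\n"),
              length(x$voltage), min(x$voltage), max(x$voltage),
              x$wavelength[1], x$wavelength[length(x$wavelength)],
              min(x$linewidth), max(x$linewidth)))
  invisible(x)
}

#' Default synthetic calibration shipped with the package
#'
#' Emulates the measured behaviour of the modeled source: wavelength
#' monotonically *decreasing* with voltage over 575-1040 nm, instantaneous
#' linewidth growing linearly from 2.5 nm (575 nm) to 9 nm (1040 nm), and a
#' smooth efficiency bump peaking near 800 nm.
#'
#' @param n_nodes number of calibration nodes
#' @return a `calibration_table`
#' @export
default_calibration <- function(n_nodes = 16) {
  v <- seq(0, 10, length.out = n_nodes)
  lam <- seq(1040, 575, length.out = n_nodes)
  lw <- 2.5 + (9 - 2.5) * (lam - 575) / (1040 - 575)
  eff <- exp(-(lam - 800)^2 / (2 * 120^2))
  calibration_table(v, lam, lw, eff / max(eff))
}

#' Calibration range helpers
#' @param table a `calibration_table`
#' @return length-2 numeric range
#' @export
calibration_wavelength_range <- function(table) range(table$wavelength)

#' @rdname calibration_wavelength_range
#' @export
calibration_voltage_range <- function(table) range(table$voltage)

check_in_range <- function(x, rng, what) {
  bad <- x < min(rng) | x > max(rng)
  if (any(bad))
    stopf("%s %.6g outside the calibrated interval [%.6g, %.6g]",
          what, x[which(bad)[1]], min(rng), max(rng))
  invisible(x)
}

v2l_fun <- function(table) {
  stats::splinefun(table$voltage, table$wavelength, method = "monoH.FC")
}

#' Center wavelength for a control voltage
#'
#' Monotone piecewise-cubic interpolation through the calibration nodes;
#' exact at the nodes and the inverse of [voltage_for_wavelength()].
#'
#' @param table a `calibration_table`
#' @param v voltages, V (within the calibrated range)
#' @return wavelengths, nm
#' @export
wavelength_for_voltage <- function(table, v) {
  stopifnot(inherits(table, "calibration_table"))
  assert_num(v, "v")
  check_in_range(v, table$voltage, "voltage")
  v2l_fun(table)(v)
}

#' Control voltage for a center wavelength
#'
#' Numerical inverse of [wavelength_for_voltage()]; exact at the nodes, and
#' round-trips through the forward map to better than 1e-6 nm.
#'
#' @param table a `calibration_table`
#' @param lam wavelengths, nm (within the calibrated range)
#' @return voltages, V
#' @export
voltage_for_wavelength <- function(table, lam) {
  stopifnot(inherits(table, "calibration_table"))
  assert_num(lam, "lam")
  check_in_range(lam, table$wavelength, "wavelength")
  f <- v2l_fun(table)
  vapply(lam, function(l) {
    i <- match(TRUE, abs(table$wavelength - l) < 1e-12)
    if (!is.na(i)) return(table$voltage[i])
    # bracket within the node interval containing l (wavelength monotone)
    wl <- table$wavelength
    if (wl[1] > wl[length(wl)]) {
      j <- findInterval(-l, -wl)
    } else {
      j <- findInterval(l, wl)
    }
    j <- min(max(j, 1L), length(wl) - 1L)
    stats::uniroot(function(v) f(v) - l,
                   lower = table$voltage[j], upper = table$voltage[j + 1L],
                   tol = 1e-13)$root
  }, numeric(1))
}

#' Interpolated instantaneous linewidth / efficiency at a wavelength
#' @param table a `calibration_table`
#' @param lam wavelengths, nm
#' @return nm FWHM (`linewidth_at`) or relative irradiance (`efficiency_at`)
#' @export
linewidth_at <- function(table, lam) {
  stopifnot(inherits(table, "calibration_table"))
  check_in_range(lam, table$wavelength, "wavelength")
  o <- order(table$wavelength)
  stats::approx(table$wavelength[o], table$linewidth[o], xout = lam)$y
}

#' @rdname linewidth_at
#' @export
efficiency_at <- function(table, lam) {
  stopifnot(inherits(table, "calibration_table"))
  check_in_range(lam, table$wavelength, "wavelength")
  o <- order(table$wavelength)
  stats::approx(table$wavelength[o], table$efficiency[o], xout = lam)$y
}

#' Instantaneous spectral line at a commanded center wavelength
#'
#' The AOTF line is modeled as a Gaussian whose FWHM is the interpolated
#' instantaneous linewidth and whose amplitude is the interpolated source
#' efficiency at the center. Its integral over an adequate grid equals
#' `efficiency * fwhm * sqrt(pi / (4 log(2)))`.
#'
#' @param table a `calibration_table`
#' @param center commanded center wavelength, nm
#' @param grid wavelength samples, nm; a warning is issued when the grid does
#'   not cover center +/- 2 FWHM (truncated integral)
#' @return an `ffoct_spectrum` on `grid`
#' @export
instantaneous_spectrum <- function(table, center, grid) {
  stopifnot(inherits(table, "calibration_table"))
  assert_num(center, "center", len = 1)
  check_in_range(center, table$wavelength, "wavelength")
  fw <- linewidth_at(table, center)
  eff <- efficiency_at(table, center)
  if (min(grid) > center - 2 * fw || max(grid) < center + 2 * fw)
    warnf("grid does not cover +/- 2 FWHM around %.4g nm; integral truncated",
          center)
  s <- fw / GAUSS_FWHM
  spectrum_density(grid, eff * exp(-(grid - center)^2 / (2 * s^2)),
                   kind = "wavelength")
}

#' Read / write calibration tables as CSV
#'
#' Column layout: `voltage_V,wavelength_nm,linewidth_nm,efficiency`.
#'
#' @param path file path
#' @return `read_calibration_csv` returns a `calibration_table`
#' @export
read_calibration_csv <- function(path) {
  d <- utils::read.csv(path)
  calibration_table(d$voltage_V, d$wavelength_nm, d$linewidth_nm, d$efficiency)
}

#' @rdname read_calibration_csv
#' @param table a `calibration_table`
#' @export
write_calibration_csv <- function(table, path) {
  stopifnot(inherits(table, "calibration_table"))
  utils::write.csv(data.frame(voltage_V = table$voltage,
                              wavelength_nm = table$wavelength,
                              linewidth_nm = table$linewidth,
                              efficiency = table$efficiency),
                   path, row.names = FALSE)
  invisible(path)
}
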
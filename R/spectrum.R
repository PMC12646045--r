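#' Sampled spectral density
#'
#' A spectrum is a non-negative density sampled on a strictly ascending grid,
#' either in wavelength (nm) or in wavenumber k = 2*pi/lambda (rad/nm).
#' Conversion between the two representations applies the Jacobian
#' |d(lambda)/dk| = lambda^2 / (2*pi) so that integrated power is preserved.
#'
#' @param grid strictly ascending sample positions, nm or rad/nm
#' @param density non-negative spectral density per grid unit
#' @param kind `"wavelength"` or `"wavenumber"`
#' @return an object of class `ffoct_spectrum` with fields `grid`, `density`,
#'   `kind`
#' @examples
#' s <- spectrum_density(seq(650, 950, 0.5), rep(1, 601))
#' spectrum_power(s)
#' @export
spectrum_density <- function(grid, density, kind = c("wavelength", "wavenumber")) {
  kind <- match.arg(kind)
  assert_num(grid, "grid")
  assert_num(density, "density", len = length(grid), nonneg = TRUE)
  if (length(grid) < 2L) stopf("a spectrum needs at least 2 samples")
  if (any(diff(grid) <= 0)) stopf("`grid` must be strictly ascending")
  structure(list(grid = grid, density = density, kind = kind),
            class = "ffoct_spectrum")
}

#' @export
print.ffoct_spectrum <- function(x, ...) {
  cat(sprintf("<ffoct_spectrum> %d samples on %s grid [%.6g, %.6g], power %.4g\n",
              length(x$grid), x$kind, min(x$grid), max(x$grid),
              spectrum_power(x)))
  invisible(x)
}

#' Integrated power of a spectrum (trapezoidal rule)
#' @param s an `ffoct_spectrum`
#' @return scalar integral of the density over the grid
#' @export
spectrum_power <- function(s) {
  stopifnot(inherits(s, "ffoct_spectrum"))
  pracma::trapz(s$grid, s$density)
}

#' Convert a spectrum to a wavenumber grid
#'
#' k = 2*pi/lambda; the density picks up the Jacobian lambda^2/(2*pi) so that
#' integrated power is preserved. The output grid is ascending in k
#' (i.e. descending in wavelength).
#'
#' @param s an `ffoct_spectrum`
#' @return an `ffoct_spectrum` with `kind = "wavenumber"`
#' @export
as_wavenumber <- function(s) {
  stopifnot(inherits(s, "ffoct_spectrum"))
  if (s$kind == "wavenumber") return(s)
  k <- rev(2 * pi / s$grid)
  dens <- rev(s$density * s$grid^2 / (2 * pi))
  spectrum_density(k, dens, kind = "wavenumber")
}

#' Convert a spectrum to a wavelength grid
#' @param s an `ffoct_spectrum`
#' @return an `ffoct_spectrum` with `kind = "wavelength"`
#' @export
as_wavelength <- function(s) {
  stopifnot(inherits(s, "ffoct_spectrum"))
  if (s$kind == "wavelength") return(s)
  lam <- rev(2 * pi / s$grid)
  dens <- rev(s$density * s$grid^2 / (2 * pi))
  spectrum_density(lam, dens, kind = "wavelength")
}

#' Read / write spectra as CSV
#'
#' Files carry the two columns `wavelength_nm,density`.
#'
#' @param path file path
#' @return `read_spectrum_csv` returns an `ffoct_spectrum`
#' @export
read_spectrum_csv <- function(path) {
  d <- utils::read.csv(path)
  spectrum_density(d$wavelength_nm, d$density, kind = "wavelength")
}

#' @rdname read_spectrum_csv
#' @param s an `ffoct_spectrum` on a wavelength grid
#' @export
write_spectrum_csv <- function(s, path) {
  s <- as_wavelength(s)
  utils::write.csv(data.frame(wavelength_nm = s$grid, density = s$density),
                   path, row.names = FALSE)
  invisible(path)
}
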
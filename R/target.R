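#' Target illumination spectrum
#'
#' Parametric or tabulated spectral shapes the source is commanded to
#' synthesize. All parametric shapes realize the *requested* spectral FWHM:
#'
#' * `rectangular`: indicator of width `fwhm` centered on `center`.
#' * `gaussian`: Gaussian of FWHM `fwhm`, truncated at a finite support of
#'   width `fwhm / 0.6` (truncation at about 1.96 sigma) so a scan stays
#'   finite.
#' * `blackman`: the (0.42, 0.5, 0.08) Blackman window over a support of
#'   width `fwhm / 0.40536`; the Blackman window's half-maximum width is
#'   0.40536 of its support, so the realized FWHM equals `fwhm`.
#' * `tabulated`: an arbitrary measured spectrum (e.g. an LED) given as an
#'   [spectrum_density()] object; `center`/`fwhm` are ignored.
#'
#' @param shape one of `"rectangular"`, `"gaussian"`, `"blackman"`,
#'   `"tabulated"`
#' @param center center wavelength, nm (parametric shapes)
#' @param fwhm full width at half maximum, nm (parametric shapes)
#' @param table an `ffoct_spectrum` for `shape = "tabulated"`
#' @return a `target_spectrum` object
#' @examples
#' tg <- target_spectrum("gaussian", center = 800, fwhm = 60)
#' target_support(tg)
#' @export
target_spectrum <- function(shape = c("rectangular", "gaussian", "blackman",
                                      "tabulated"),
                            center = NULL, fwhm = NULL, table = NULL) {
  shape <- match.arg(shape)
  if (shape == "tabulated") {
    if (!inherits(table, "ffoct_spectrum"))
      stopf("tabulated target needs `table`, an ffoct_spectrum")
    table <- as_wavelength(table)
  } else {
    assert_num(center, "center", len = 1, positive = TRUE)
    assert_num(fwhm, "fwhm", len = 1, positive = TRUE)
  }
  structure(list(shape = shape, center = center, fwhm = fwhm, table = table),
            class = "target_spectrum")
}

# Blackman window half-maximum width as a fraction of its support.
BLACKMAN_FWHM_FRACTION <- 0.40536

#' Support of a target spectrum
#' @param target a `target_spectrum`
#' @return length-2 numeric, the wavelength interval (nm) outside which the
#'   target density is zero
#' @export
target_support <- function(target) {
  stopifnot(inherits(target, "target_spectrum"))
  with(target, switch(shape,
    rectangular = center + c(-0.5, 0.5) * fwhm,
    gaussian    = center + c(-0.5, 0.5) * fwhm / 0.6,
    blackman    = center + c(-0.5, 0.5) * fwhm / BLACKMAN_FWHM_FRACTION,
    tabulated   = {
      nz <- which(table$density > 0)
      range(table$grid[nz])
    }))
}

#' Evaluate a target spectrum on a wavelength grid
#' @param target a `target_spectrum`
#' @param grid wavelengths, nm
#' @return an `ffoct_spectrum` on `grid`, peak-normalized to 1
#' @export
sample_target <- function(target, grid) {
  stopifnot(inherits(target, "target_spectrum"))
  assert_num(grid, "grid")
  sup <- target_support(target)
  dens <- with(target, switch(shape,
    rectangular = as.numeric(grid >= sup[1] & grid <= sup[2]),
    gaussian = {
      s <- fwhm / GAUSS_FWHM
      exp(-(grid - center)^2 / (2 * s^2)) * (grid >= sup[1] & grid <= sup[2])
    },
    blackman = {
      w <- sup[2] - sup[1]
      th <- 2 * pi * (grid - center) / w
      (0.42 + 0.5 * cos(th) + 0.08 * cos(2 * th)) *
        (grid >= sup[1] & grid <= sup[2])
    },
    tabulated = {
      y <- stats::approx(table$grid, table$density, xout = grid, rule = 2)$y
      y[grid < sup[1] | grid > sup[2]] <- 0
      y
    }))
  dens[dens < 0] <- 0
  if (max(dens) > 0) dens <- dens / max(dens)
  spectrum_density(grid, dens, kind = "wavelength")
}
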
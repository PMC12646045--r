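#' Temporal coherence length of a spectral line
#'
#' Axial extent of the interference envelope. The default convention is
#' `lc = lambda0^2 / (2 * dlambda)`; the alternative `"gaussian_fwhm"`
#' convention returns the FWHM of the fringe envelope of a Gaussian spectrum,
#' `lc = (4 log(2) / pi) * lambda0^2 / dlambda` (about 0.88 lambda0^2/dlambda),
#' and is provided as a documented option only.
#'
#' @param center center wavelength lambda0, nm
#' @param fwhm spectral FWHM dlambda, nm
#' @param convention `"basic"` (default) or `"gaussian_fwhm"`
#' @return coherence length in micrometers
#' @examples
#' coherence_length(800, 30)   # 10.67 um
#' @export
coherence_length <- function(center, fwhm, convention = c("basic", "gaussian_fwhm")) {
  convention <- match.arg(convention)
  assert_num(center, "center", positive = TRUE)
  assert_num(fwhm, "fwhm", positive = TRUE)
  nm <- switch(convention,
    basic = center^2 / (2 * fwhm),
    gaussian_fwhm = (4 * log(2) / pi) * center^2 / fwhm)
  nm / 1000
}

#' Spectral FWHM needed for a prescribed coherence length
#'
#' Inverse of [coherence_length()] under the `"basic"` convention:
#' `dlambda = lambda0^2 / (2 * lc)`.
#'
#' @param center center wavelength, nm
#' @param lc coherence length, um
#' @return spectral FWHM, nm
#' @export
fwhm_for_coherence_length <- function(center, lc) {
  assert_num(center, "center", positive = TRUE)
  assert_num(lc, "lc", positive = TRUE)
  center^2 / (2 * lc * 1000)
}

#' Step-index multimode fiber description
#' @param core_diameter core diameter, um
#' @param numerical_aperture NA, dimensionless
#' @param length fiber length, m
#' @return a `fiber_spec` object
#' @export
fiber_spec <- function(core_diameter = 200, numerical_aperture = 0.39,
                       length = 100) {
  assert_num(core_diameter, "core_diameter", len = 1, positive = TRUE)
  assert_num(numerical_aperture, "numerical_aperture", len = 1, positive = TRUE)
  assert_num(length, "length", len = 1, positive = TRUE)
  structure(list(core_diameter = core_diameter,
                 numerical_aperture = numerical_aperture, length = length),
            class = "fiber_spec")
}

#' Number of guided spatial modes of a step-index fiber
#'
#' Uses the V-number convention M = V^2 / 2 per polarization, with
#' V = pi * d * NA / lambda. The wavelength is always an explicit argument:
#' a 200 um / 0.39 NA fiber supports about 41.6e3 modes at 850 nm.
#'
#' @param fiber a [fiber_spec()]
#' @param lam wavelength, nm
#' @return mode count (not rounded)
#' @export
fiber_mode_count <- function(fiber, lam) {
  stopifnot(inherits(fiber, "fiber_spec"))
  assert_num(lam, "lam", positive = TRUE)
  v <- pi * (fiber$core_diameter * 1000) * fiber$numerical_aperture / lam
  v^2 / 2
}

#' Multimode speckle pattern and its contrast
#'
#' Each speckle realization is fully developed: the field at every pixel is
#' the sum of `n_modes` independent circular complex Gaussian mode amplitudes
#' (variance 1/n_modes each), so the summed field is unit-power circular
#' Gaussian and a single pattern has intensity contrast 1. Active mode mixing
#' is emulated by averaging `n_averages` independent intensity patterns,
#' which reduces the contrast as 1/sqrt(n_averages).
#'
#' @param n_modes number of mode phasors summed per pixel (>= 1)
#' @param n_averages number of independent patterns averaged (>= 1)
#' @param image_shape integer length-2, pattern size in pixels
#' @param seed RNG seed for reproducibility
#' @return list with `image` (matrix, mean intensity) and `contrast`
#'   (sd/mean over pixels)
#' @examples
#' sp <- speckle_contrast(8, 100, c(64, 64), seed = 1)
#' sp$contrast  # about 0.1
#' @export
speckle_contrast <- function(n_modes, n_averages, image_shape = c(256, 256),
                             seed = 1) {
  assert_num(n_modes, "n_modes", len = 1, positive = TRUE)
  assert_num(n_averages, "n_averages", len = 1, positive = TRUE)
  npix <- prod(image_shape)
  set.seed(seed)
  acc <- matrix(0, image_shape[1], image_shape[2])
  for (a in seq_len(n_averages)) {
    re <- matrix(stats::rnorm(npix * n_modes, sd = sqrt(0.5 / n_modes)),
                 npix, n_modes)
    im <- matrix(stats::rnorm(npix * n_modes, sd = sqrt(0.5 / n_modes)),
                 npix, n_modes)
    field <- complex(real = rowSums(re), imaginary = rowSums(im))
    acc <- acc + matrix(Mod(field)^2, image_shape[1], image_shape[2])
  }
  img <- acc / n_averages
  list(image = img, contrast = stats::sd(img) / mean(img))
}
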
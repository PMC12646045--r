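#' Mie efficiencies of a homogeneous sphere
#'
#' Exact Mie series for a non-absorbing sphere of size parameter `x` and
#' relative refractive index `m` (real). The scattering coefficients `a_n`,
#' `b_n` are computed from the logarithmic derivative `D_n(mx)` by downward
#' recurrence (started well above the truncation order) and
#' Riccati-Bessel functions `psi_n`, `chi_n` of the *size parameter* by
#' upward recurrence, which is stable for real x. The series is truncated at
#' `n_max = ceiling(x + 4 x^(1/3) + 2)`.
#'
#' The backscattering efficiency is
#' `Q_back = (1/x^2) |sum_n (2n+1) (-1)^n (a_n - b_n)|^2`.
#'
#' @param x size parameter `pi * d * n_medium / lambda`, in (0, 500)
#' @param m relative index `n_particle / n_medium` (real, > 0)
#' @return list with `q_ext`, `q_sca`, `q_back` (vectorized over `x`)
#' @examples
#' mie_efficiencies(0.01, 1.5)$q_back  # Rayleigh regime: 4 x^4 |(m^2-1)/(m^2+2)|^2
#' @export
mie_efficiencies <- function(x, m) {
  assert_num(x, "x", positive = TRUE)
  assert_num(m, "m", len = 1, positive = TRUE)
  if (any(x >= 500)) stopf("size parameter must be < 500")
  if (abs(m - 1) < 1e-12) {
    z <- rep(0, length(x))
    return(structure(list(q_ext = z, q_sca = z, q_back = z),
                     index_matched = TRUE))
  }
  out <- vapply(x, function(xi) mie_single(xi, m), numeric(3))
  list(q_ext = out[1, ], q_sca = out[2, ], q_back = out[3, ])
}

mie_single <- function(x, m) {
  if (abs(m - 1) < 1e-12) return(c(0, 0, 0))
  nmax <- ceiling(x + 4 * x^(1/3) + 2)
  mx <- m * x
  # logarithmic derivative by downward recurrence
  nstart <- max(nmax, ceiling(abs(mx))) + 15L
  d <- numeric(nstart + 1L)            # d[n+1] = D_n(mx); D_nstart = 0
  for (n in nstart:1) {
    r <- n / mx
    d[n] <- r - 1 / (d[n + 1L] + r)
  }
  # Riccati-Bessel psi_n(x), chi_n(x) upward
  psi_m1 <- cos(x); psi0 <- sin(x)
  chi_m1 <- -sin(x); chi0 <- cos(x)
  qe <- 0; qs <- 0; bsum <- 0i
  psi_prev <- psi_m1; psi <- psi0
  chi_prev <- chi_m1; chi <- chi0
  for (n in seq_len(nmax)) {
    psi_n <- (2 * n - 1) / x * psi - psi_prev
    chi_n <- (2 * n - 1) / x * chi - chi_prev
    xi_n <- complex(real = psi_n, imaginary = -chi_n)
    xi_nm1 <- complex(real = psi, imaginary = -chi)
    dn <- d[n + 1L]
    ta <- dn / m + n / x
    tb <- dn * m + n / x
    a_n <- (ta * psi_n - psi) / (ta * xi_n - xi_nm1)
    b_n <- (tb * psi_n - psi) / (tb * xi_n - xi_nm1)
    qe <- qe + (2 * n + 1) * Re(a_n + b_n)
    qs <- qs + (2 * n + 1) * (Mod(a_n)^2 + Mod(b_n)^2)
    bsum <- bsum + (2 * n + 1) * (-1)^n * (a_n - b_n)
    psi_prev <- psi; psi <- psi_n
    chi_prev <- chi; chi <- chi_n
  }
  c(2 / x^2 * qe, 2 / x^2 * qs, Mod(bsum)^2 / x^2)
}

#' Spectral backscattering efficiency of a sphere
#'
#' Evaluates `Q_back(lambda)` for a sphere of the given diameter across a
#' wavelength grid; this is the quantity the FFOCT particle signal is
#' proportional to. Default indices are polystyrene beads (1.59) in an
#' agar/water medium (1.34); `sigma = TRUE` returns the backscattering
#' cross-section `Q_back * pi (d/2)^2` (nm^2) instead.
#'
#' @param diameter sphere diameter, nm
#' @param wavelengths vacuum wavelengths, nm
#' @param particle_index refractive index of the sphere (scalar or one per
#'   wavelength)
#' @param medium_index refractive index of the medium
#' @param sigma return the cross-section instead of the efficiency
#' @return data.frame with columns `wavelength_nm` and `q_back` (or
#'   `sigma_back_nm2`)
#' @examples
#' mie_backscatter(990, seq(750, 950, 25))
#' @export
mie_backscatter <- function(diameter, wavelengths, particle_index = 1.59,
                            medium_index = 1.34, sigma = FALSE) {
  assert_num(diameter, "diameter", len = 1, positive = TRUE)
  assert_num(wavelengths, "wavelengths", positive = TRUE)
  if (!length(particle_index) %in% c(1L, length(wavelengths)))
    stopf("`particle_index` must be scalar or one value per wavelength")
  np <- rep(particle_index, length.out = length(wavelengths))
  qb <- vapply(seq_along(wavelengths), function(i) {
    x <- pi * diameter * medium_index / wavelengths[i]
    mie_single(x, np[i] / medium_index)[3]
  }, numeric(1))
  if (sigma) {
    data.frame(wavelength_nm = wavelengths,
               sigma_back_nm2 = qb * pi * (diameter / 2)^2)
  } else {
    data.frame(wavelength_nm = wavelengths, q_back = qb)
  }
}
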
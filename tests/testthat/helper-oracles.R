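# Independent oracles used across the suite. These deliberately take
# different numerical routes from the package implementation.

# Piecewise-linear interpolation through (x, y) nodes.
oracle_pwlinear <- function(x_nodes, y_nodes, x) {
  vapply(x, function(xi) {
    j <- max(which(x_nodes <= xi + 1e-15))
    if (j == length(x_nodes)) return(y_nodes[j])
    t <- (xi - x_nodes[j]) / (x_nodes[j + 1] - x_nodes[j])
    (1 - t) * y_nodes[j] + t * y_nodes[j + 1]
  }, numeric(1))
}

# Fourier magnitude of a sampled spectral density by brute-force summation
# with trapezoid weights (independent of the fringe/demodulation chain).
oracle_ft_magnitude <- function(k, s, opd_nm) {
  w <- c(diff(k) / 2, 0) + c(0, diff(k) / 2)
  s <- s * w / sum(s * w)
  vapply(opd_nm, function(d) Mod(sum(s * exp(1i * k * d))), numeric(1))
}

# Riccati-Bessel Mie coefficients via half-integer Bessel functions
# (Bohren & Huffman route; upward, no logarithmic derivative).
oracle_mie <- function(x, m) {
  nmax <- ceiling(x + 4 * x^(1/3) + 2)
  n <- seq_len(nmax)
  psi <- function(nn, z) sqrt(pi * z / 2) * besselJ(z, nn + 0.5)
  chi <- function(nn, z) -sqrt(pi * z / 2) * besselY(z, nn + 0.5)
  ps_x <- psi(n, x); ps_xm1 <- psi(n - 1, x)
  ch_x <- chi(n, x); ch_xm1 <- chi(n - 1, x)
  xi_x <- complex(real = ps_x, imaginary = -ch_x)
  xi_xm1 <- complex(real = ps_xm1, imaginary = -ch_xm1)
  mx <- m * x
  ps_mx <- psi(n, mx); ps_mxm1 <- psi(n - 1, mx)
  dps_x <- ps_xm1 - n * ps_x / x
  dps_mx <- ps_mxm1 - n * ps_mx / mx
  dxi_x <- xi_xm1 - n * xi_x / x
  a <- (m * ps_mx * dps_x - ps_x * dps_mx) /
       (m * ps_mx * dxi_x - xi_x * dps_mx)
  b <- (ps_mx * dps_x - m * ps_x * dps_mx) /
       (ps_mx * dxi_x - m * xi_x * dps_mx)
  list(
    q_ext = 2 / x^2 * sum((2 * n + 1) * Re(a + b)),
    q_sca = 2 / x^2 * sum((2 * n + 1) * (Mod(a)^2 + Mod(b)^2)),
    q_back = Mod(sum((2 * n + 1) * (-1)^n * (a - b)))^2 / x^2)
}

# Least-squares sinusoid fit I_p = c0 + A cos(phi_p + theta); returns A.
oracle_sinusoid_amplitude <- function(phases, intensities) {
  X <- cbind(1, cos(phases), sin(phases))
  beta <- solve(crossprod(X), crossprod(X, intensities))
  sqrt(beta[2]^2 + beta[3]^2)
}

# Flat-efficiency calibration over 575-1040 nm with constant linewidth.
flat_table <- function(lw = 5, eff = c(1, 1)) {
  calibration_table(c(0, 10), c(575, 1040), c(lw, lw), eff)
}

# Quick RMS between a designed-and-predicted spectrum and its ideal target,
# both peak-normalized, over the support plus a 20% margin.
roundtrip_rms <- function(target, table, n_steps = 64, exposure = 30000) {
  sq <- design_td_sequence(target, table, exposure = exposure,
                           n_steps = n_steps)
  sup <- target_support(target)
  span <- diff(sup)
  grid <- seq(sup[1] - 0.2 * span, sup[2] + 0.2 * span, length.out = 1200)
  pred <- predict_integrated_spectrum(sq, table, grid)
  ideal <- sample_target(target, grid)
  sqrt(mean((pred$density - ideal$density)^2))
}
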
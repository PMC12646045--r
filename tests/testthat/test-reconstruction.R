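test_that("4-phase demodulation recovers amplitudes independent of phase offset", {
  set.seed(13)
  phases4 <- c(0, pi / 2, pi, 3 * pi / 2)
  for (i in 1:100) {
    a0 <- runif(1, 0.01, 2)
    th <- runif(1, 0, 2 * pi)
    dc <- runif(1, 1, 10)
    ii <- lapply(phases4, function(p) dc + a0 * cos(th + p))
    fr <- structure(list(phases = phases4, intensities = ii,
                         reference_reflectivity = 1),
                    class = "phase_stepped_frames")
    expect_equal(demodulate_phases(fr), a0, tolerance = 1e-12)
    # least-squares sinusoid fit oracle agrees
    expect_equal(oracle_sinusoid_amplitude(phases4, unlist(ii)), a0,
                 tolerance = 1e-9)
  }
  # all-equal frames demodulate to zero
  fr0 <- structure(list(phases = phases4, intensities = as.list(rep(5, 4)),
                        reference_reflectivity = 1),
                   class = "phase_stepped_frames")
  expect_equal(demodulate_phases(fr0), 0)
  # 2-phase variant
  fr2 <- structure(list(phases = c(0, pi), intensities = list(7, 3),
                        reference_reflectivity = 1),
                   class = "phase_stepped_frames")
  expect_equal(demodulate_phases(fr2), 2)
  fr2$phases <- c(0, pi / 3)
  expect_error(demodulate_phases(fr2), "phases")
})

test_that("swept-source reconstruction localizes mirrors and stabilizes with zero padding", {
  tab <- calibration_table(c(0, 10), c(575, 1040), c(1e-6, 1e-6), c(1, 1))
  plan <- design_k_linear_sweep(650, 950, 250, tab)
  dz <- 2 * pi / (250 * plan_dk(plan)) / 2 / 1000  # coarse depth bin, um

  st <- simulate_ss_stack(phantom(9), plan, tab)
  pr1 <- ss_reconstruct(st, window = "none", zero_pad = 1)
  pr8 <- ss_reconstruct(st, window = "none", zero_pad = 8)
  peak_at <- function(p) p$depth_grid[which.max(p$amplitude)]
  expect_lt(abs(peak_at(pr1) - 9), dz)
  expect_lt(abs(peak_at(pr8) - 9), dz / 8)
  expect_lt(abs(peak_at(pr8) - peak_at(pr1)), dz)

  # 50 random mirror depths localize within a quarter of the coarse bin
  set.seed(17)
  for (z0 in runif(50, 2, 55)) {
    p <- ss_reconstruct(simulate_ss_stack(phantom(z0), plan, tab),
                        window = "none", zero_pad = 8)
    expect_lt(abs(peak_at(p) - z0), dz / 4)
  }
})

test_that("two-mirror reconstruction preserves amplitude ratios and Parseval energy", {
  tab <- calibration_table(c(0, 10), c(575, 1040), c(1e-6, 1e-6), c(1, 1))
  plan <- design_k_linear_sweep(650, 950, 250, tab)
  ph <- phantom(c(8, 40), c(0.24, 0.08))
  st <- simulate_ss_stack(ph, plan, tab)
  pr <- ss_reconstruct(st, window = "blackman", zero_pad = 16)
  pk <- function(z0) max(pr$amplitude[abs(pr$depth_grid - z0) < 2])
  expect_equal(pk(8) / pk(40), 3, tolerance = 0.01)

  # Parseval: windowed k-signal energy equals transform energy / N_pad
  sig <- pr$meta$windowed_signal
  tr <- pr$meta$full_fft
  expect_equal(sum(sig^2), sum(Mod(tr)^2) / length(tr), tolerance = 1e-9)

  # non-uniform k grids are rejected
  bad <- st
  bad$plan$wavenumbers[3] <- bad$plan$wavenumbers[3] * 1.001
  expect_error(ss_reconstruct(bad), "uniform")
})

test_that("profile FWHM agrees with closed forms and converges under refinement", {
  # Gaussian profile of known sigma
  z <- seq(0, 40, 0.01)
  sig <- 2.7
  pr <- axial_profile(z, exp(-(z - 20)^2 / (2 * sig^2)))
  expect_equal(fwhm(pr), ffoctsim:::GAUSS_FWHM * sig, tolerance = 0.005)
  zf <- seq(0, 40, 0.001)
  prf <- axial_profile(zf, exp(-(zf - 20)^2 / (2 * sig^2)))
  expect_equal(fwhm(prf), fwhm(pr), tolerance = 0.005)
  # peak at the edge errors
  expect_error(fwhm(axial_profile(z, exp(-z / 5))), "edge")

  # sinc profile from a flat k-band: depth FWHM = 3.791 / dk
  k <- seq(2 * pi / 950, 2 * pi / 650, length.out = 3001)
  sp <- spectrum_density(k, rep(1, 3001), "wavenumber")
  pr2 <- simulate_axial_scan(phantom(6), sp, seq(8, 16, 0.002))
  dk <- (max(k) - min(k)) * 1000
  expect_equal(fwhm(pr2), 3.7909885 / dk, tolerance = 0.002)
})

test_that("peak sidelobe levels match window theory", {
  k <- seq(2 * pi / 950, 2 * pi / 650, length.out = 3001)
  sp <- spectrum_density(k, rep(1, 3001), "wavenumber")
  opd <- seq(0, 30, 0.005)
  pr <- simulate_axial_scan(phantom(6), sp, opd)
  # unwindowed rectangular band: sinc first sidelobe at -13.26 dB
  expect_equal(as.numeric(peak_sidelobe_db(pr)), 20 * log10(0.21723),
               tolerance = 0.01)

  # Blackman-shaped spectrum: at least 10 dB below the rectangular case
  tg <- target_spectrum("blackman", 800, 120)
  sup <- target_support(tg)
  spb <- sample_target(tg, seq(sup[1] - 5, sup[2] + 5, length.out = 2500))
  prb <- simulate_axial_scan(phantom(0), spb, seq(-40, 40, 0.02))
  expect_lte(as.numeric(peak_sidelobe_db(prb)), -23.3)

  # pure Gaussian profile: no sidelobes, floor flag
  z <- seq(0, 40, 0.02)
  prg <- axial_profile(z, exp(-(z - 20)^2 / 18))
  sl <- peak_sidelobe_db(prg)
  expect_true(isTRUE(attr(sl, "floor")))
})

test_that("roll-off follows the Gaussian washout model of the instantaneous line", {
  # dense-node table whose envelope FWHM is 72 um of OPD at every frame
  lam <- seq(575, 1040, length.out = 200)
  lw <- 8 * log(2) / (72 * 1000 * 2 * pi) * lam^2
  tb <- calibration_table(seq(0, 10, length.out = 200), lam, lw,
                          rep(1, 200))
  plan <- design_k_linear_sweep(650, 950, 250, tb)
  rc <- rolloff_curve(c(5, 28, 55), plan, tb, zero_pad = 8)
  # the quoted roll-off figure: about -13.9 dB at 55 um of optical path
  expect_equal(rc$peak_db[3], -13.9, tolerance = 0.04)
  expect_true(all(diff(rc$peak_db) < 0))
  # log attenuation is quadratic in linewidth: doubling the linewidth
  # quadruples (not doubles) the dB at fixed OPD for a Gaussian line --
  # checked against the closed form
  att <- function(scale) {
    tb2 <- calibration_table(seq(0, 10, length.out = 200), lam, scale * lw,
                             rep(1, 200))
    rolloff_curve(c(5, 28), design_k_linear_sweep(650, 950, 250, tb2),
                  tb2, zero_pad = 8)$peak_db[2]
  }
  expect_equal(att(2) / att(1), 4, tolerance = 0.1)

  # zero linewidth: flat curve
  tb0 <- calibration_table(c(0, 10), c(575, 1040), c(1e-6, 1e-6), c(1, 1))
  rc0 <- rolloff_curve(c(5, 28, 55), design_k_linear_sweep(650, 950, 250, tb0),
                       tb0, window = "blackman", zero_pad = 16)
  expect_lt(max(abs(rc0$peak_db)), 0.05)
  expect_error(rolloff_curve(500, plan, tb), "Nyquist")
})

test_that("depth range follows the conjugate-free Nyquist convention", {
  expect_equal(depth_range(250, 650, 950), 64.07, tolerance = 1e-3)
  expect_equal(depth_range(500, 650, 950) / depth_range(250, 650, 950),
               499 / 249)
  expect_gt(depth_range(2, 650, 950), 0)
  expect_equal(depth_range(250, 650, 950, conjugate_free = FALSE),
               2 * depth_range(250, 650, 950))
  expect_error(depth_range(1, 650, 950))
})
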
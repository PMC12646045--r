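test_that("fringe envelope matches closed forms for rectangular and Gaussian spectra", {
  # rectangular band, flat in k: |gamma| = |sinc(dk * OPD / 2)|
  k <- seq(2 * pi / 950, 2 * pi / 650, length.out = 4001)
  dk <- max(k) - min(k)
  sp <- spectrum_density(k, rep(1, length(k)), kind = "wavenumber")
  opd <- seq(0, 10, 0.05)
  g <- Mod(fringe_envelope(sp, opd))
  x <- dk * opd * 1000 / 2
  sinc <- ifelse(x == 0, 1, abs(sin(x) / x))
  expect_lt(max(abs(g - sinc)), 1e-6)
  expect_equal(g[1], 1)
  # first zero at OPD = 2 pi / dk
  expect_lt(Mod(fringe_envelope(sp, 2 * pi / dk / 1000)), 1e-4)

  # Gaussian spectrum: Gaussian envelope with OPD-FWHM = 8 log 2 / dk_fwhm
  kf <- 3e-4
  sg <- spectrum_density(k, exp(-(k - mean(k))^2 /
                                (2 * (kf / ffoctsim:::GAUSS_FWHM)^2)),
                         kind = "wavenumber")
  opd2 <- seq(0, 40, 0.02)
  env <- Mod(fringe_envelope(sg, opd2))
  w <- ffoctsim:::half_max_width(c(-rev(opd2[-1]), opd2),
                                 c(rev(env[-1]), env))
  expect_equal(w, 8 * log(2) / kf / 1000, tolerance = 1e-3)

  expect_error(fringe_envelope(spectrum_density(k, rep(0, length(k)),
                                                "wavenumber"), 1),
               "zero")
})

test_that("phase-stepped frames obey the interferometric closed forms", {
  k <- seq(2 * pi / 950, 2 * pi / 650, length.out = 2001)
  sp <- spectrum_density(k, rep(1, length(k)), kind = "wavenumber")
  # single mirror at matched OPD: I_0 - I_pi = 4 sqrt(R_ref R_s)
  ph <- phantom(5, sqrt(0.5))
  fr <- td_frames(ph, sp, reference_opd = 10, phases = c(0, pi), r_ref = 0.3)
  expect_equal(fr$intensities[[1]] - fr$intensities[[2]],
               4 * sqrt(0.3 * 0.5), tolerance = 1e-9)
  # no reflectors: all phases identical
  fr0 <- td_frames(phantom(numeric(0), numeric(0)), sp, 3)
  expect_equal(length(unique(unlist(fr0$intensities))), 1L)
})

test_that("multi-reflector signals superpose (brute-force oracle)", {
  k <- seq(2 * pi / 950, 2 * pi / 650, length.out = 1201)
  sp <- spectrum_density(k, exp(-(k - mean(k))^2 / (2 * 2e-4^2)),
                         kind = "wavenumber")
  set.seed(8)
  for (rep_i in 1:5) {
    z <- sort(runif(2, 2, 12))
    a <- runif(2, 0.1, 1)
    ph12 <- phantom(z, a)
    ro <- runif(1, 5, 20)
    fr <- td_frames(ph12, sp, ro)
    # oracle: sum single-reflector AC terms plus combined DC
    single <- lapply(1:2, function(i) td_frames(phantom(z[i], a[i]), sp, ro))
    for (p in 1:4) {
      dc_each <- 1 + a^2
      ac_sum <- sum(vapply(1:2, function(i)
        single[[i]]$intensities[[p]] - dc_each[i], numeric(1)))
      expect_equal(fr$intensities[[p]], 1 + sum(a^2) + ac_sum,
                   tolerance = 1e-12)
    }
  }
})

test_that("TD axial scan of a mirror equals the Fourier magnitude of the spectrum", {
  k <- seq(2 * pi / 950, 2 * pi / 650, length.out = 1501)
  dens <- pmax(0.42 - 0.5 * cos(2 * pi * seq(0, 1, length.out = 1501)) +
                 0.08 * cos(4 * pi * seq(0, 1, length.out = 1501)), 0)
  sp <- spectrum_density(k, dens, kind = "wavenumber")
  opd <- seq(0, 30, 0.05)
  pr <- simulate_axial_scan(phantom(0), sp, opd)
  oracle <- oracle_ft_magnitude(k, dens, opd * 1000)
  expect_lt(max(abs(pr$amplitude / max(pr$amplitude) -
                    oracle / max(oracle))), 1e-6)
  # empty phantom scans to zero
  pr0 <- simulate_axial_scan(phantom(numeric(0), numeric(0)), sp,
                             seq(0, 5, 0.5))
  expect_equal(max(pr0$amplitude), 0)
})

test_that("equal-FWHM spectral shapes share the axial resolution scale with descending sidelobes", {
  shapes <- c("rectangular", "gaussian", "blackman")
  prof <- lapply(shapes, function(s) {
    tg <- target_spectrum(s, 800, 120)
    sup <- target_support(tg)
    sp <- sample_target(tg, seq(sup[1] - 5, sup[2] + 5, length.out = 2500))
    simulate_axial_scan(phantom(0), sp, seq(-40, 40, 0.02))
  })
  fw <- vapply(prof, fwhm, numeric(1))
  sl <- vapply(prof, function(p) as.numeric(peak_sidelobe_db(p)), numeric(1))
  # main lobes agree to the ~25% level dictated by the window transforms
  expect_lt(diff(range(fw)) / max(fw), 0.30)
  # sidelobes descend by at least 10 dB per shape
  expect_lte(sl[2], sl[1] - 10)
  expect_lte(sl[3], sl[2] - 10)
})

test_that("swept-source stacks reduce to cosines and wash out with linewidth", {
  # vanishing linewidth: pure cosine in k
  tab <- calibration_table(c(0, 10), c(575, 1040), c(1e-6, 1e-6), c(1, 1))
  plan <- design_k_linear_sweep(650, 950, 128, tab)
  st <- simulate_ss_stack(phantom(9, 0.4), plan, tab, r_ref = 0.5)
  ac <- st$frames - st$reference_frames
  expect_equal(ac, 2 * sqrt(0.5) * 0.4 * cos(plan$wavenumbers * 18 * 1000),
               tolerance = 1e-9)

  # finite linewidth: visibility decays monotonically with OPD and matches
  # the fringe envelope of the instantaneous line
  tab6 <- calibration_table(c(0, 10), c(575, 1040), c(6, 6), c(1, 1))
  vis <- function(opd) {
    s <- simulate_ss_stack(phantom(opd / 2), plan_mid, tab6)
    max(abs(s$frames - s$reference_frames)) / 2
  }
  plan_mid <- design_k_linear_sweep(650, 950, 64, tab6)
  v <- vapply(c(0, 10, 25, 55), vis, numeric(1))
  expect_true(all(diff(v) < 0))
  g <- seq(770, 830, 0.02)
  line <- instantaneous_spectrum(tab6, 800, g)
  env55 <- Mod(fringe_envelope(line, 55))
  expect_equal(ffoctsim:::line_visibility(800, 6, 55), env55,
               tolerance = 5e-3)

  # seeded shot noise reproduces; noiseless run is analytic
  st1 <- simulate_ss_stack(phantom(5), plan, tab, full_well = 2e5, seed = 4)
  st2 <- simulate_ss_stack(phantom(5), plan, tab, full_well = 2e5, seed = 4)
  expect_identical(st1$frames, st2$frames)
  expect_false(identical(
    st1$frames,
    simulate_ss_stack(phantom(5), plan, tab, full_well = 2e5, seed = 5)$frames))
})
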
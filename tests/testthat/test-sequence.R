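test_that("dwells follow the target density and conserve the exposure", {
  tab <- flat_table(lw = 2)
  # rectangular target with flat efficiency: all dwells equal
  sq <- design_td_sequence(target_spectrum("rectangular", 800, 200), tab,
                           exposure = 19200, n_steps = 64)
  expect_equal(length(unique(sq$steps$dwell_us)), 1L)
  expect_equal(sum(sq$steps$dwell_us), 19200)
  expect_false(is.unsorted(sq$steps$wavelength_nm))

  # Gaussian target: dwell at the center is twice the dwell at +/- FWHM/2
  sqg <- design_td_sequence(target_spectrum("gaussian", 800, 120), tab,
                            exposure = 241 * 300, n_steps = 241)
  st <- sqg$steps
  d_at <- function(lam) st$dwell_us[which.min(abs(st$wavelength_nm - lam))]
  expect_equal(d_at(800) / d_at(740), 2, tolerance = 0.05)
  expect_equal(d_at(800) / d_at(860), 2, tolerance = 0.05)

  # dwell conservation for an arbitrary target
  expect_lte(abs(sum(sqg$steps$dwell_us) - 241 * 300), sqg$min_dwell)
})

test_that("dwells compensate the source efficiency profile", {
  # triangular efficiency peaking mid-band; piecewise-linear so the
  # interpolated profile is exact
  tab <- calibration_table(c(0, 5, 10), c(575, 807.5, 1040),
                           rep(3, 3), c(0.2, 1, 0.2))
  sq <- design_td_sequence(target_spectrum("rectangular", 807.5, 200), tab,
                           exposure = 3 * 64 * 400, n_steps = 64)
  prod <- sq$steps$dwell_us * efficiency_at(tab, sq$steps$wavelength_nm)
  expect_lt(diff(range(prod)) / mean(prod), 0.02)  # constant within quantization
})

test_that("shaping errors are raised for dead bands and sub-linewidth targets", {
  dead <- calibration_table(c(0, 5, 10), c(575, 807.5, 1040),
                            rep(3, 3), c(1, 0, 1))
  expect_error(design_td_sequence(target_spectrum("rectangular", 807.5, 100),
                                  dead, exposure = 6000, n_steps = 65),
               "zero")
  tab <- flat_table(lw = 8)
  expect_warning(design_td_sequence(target_spectrum("gaussian", 800, 5),
                                    tab, exposure = 6000),
                 "cannot narrow")
  expect_error(design_td_sequence(target_spectrum("rectangular", 600, 200),
                                  tab, exposure = 6000), "range")
})

test_that("predicted integrated spectrum of a single step is the line itself", {
  tab <- flat_table(lw = 5)
  sq <- voltage_sequence(data.frame(voltage_V = voltage_for_wavelength(tab, 800),
                                    wavelength_nm = 800, dwell_us = 300),
                         exposure = 300)
  g <- seq(780, 820, 0.05)
  pred <- predict_integrated_spectrum(sq, tab, g)
  line <- instantaneous_spectrum(tab, 800, g)
  expect_equal(pred$density, line$density / max(line$density),
               tolerance = 1e-12)
})

test_that("designed sequences reproduce smooth targets and approach the rectangle's smoothing floor", {
  tab <- flat_table(lw = 10)  # linewidth = FWHM/10 for 100 nm targets
  expect_lt(roundtrip_rms(target_spectrum("gaussian", 800, 100), tab), 0.05)
  expect_lt(roundtrip_rms(target_spectrum("blackman", 800, 100), tab), 0.05)
  # LED-like tabulated target (32 nm FWHM) with the real shipped linewidths
  led <- read_spectrum_csv(system.file("extdata", "led_850_spectrum.csv",
                                       package = "ffoctsim"))
  tab32 <- flat_table(lw = 3.2)
  expect_lt(roundtrip_rms(target_spectrum("tabulated", table = led), tab32),
            0.05)
  # the rectangle cannot beat the edge-smoothing floor of the Gaussian line
  # (about 0.10 RMS at linewidth = FWHM/10) but must stay near it
  rms_rect <- roundtrip_rms(target_spectrum("rectangular", 800, 100), tab)
  expect_gt(rms_rect, 0.05)
  expect_lt(rms_rect, 0.15)
})

test_that("timing-delay compensation shifts the command timeline once", {
  tab <- flat_table()
  sq <- design_td_sequence(target_spectrum("rectangular", 800, 100), tab,
                           exposure = 9600, n_steps = 32)
  sq2 <- apply_timing_delays(sq)
  expect_equal(sq2$steps$t_command_us[1], -53)  # 50 us RF + 3 us acoustic
  expect_equal(sq2$steps$t_command_us, sq2$steps$t_start_us - 53)
  expect_equal(sum(sq2$steps$dwell_us), sum(sq$steps$dwell_us))
  expect_identical(apply_timing_delays(sq2), sq2)  # idempotent
  sq0 <- voltage_sequence(sq$steps, sq$exposure, rf_delay = 0,
                          acoustic_delay = 0)
  expect_equal(apply_timing_delays(sq0)$steps$t_command_us,
               sq0$steps$t_start_us)
})

test_that("sequence CSV export round-trips the schedule", {
  tab <- flat_table()
  sq <- apply_timing_delays(
    design_td_sequence(target_spectrum("gaussian", 800, 80), tab,
                       exposure = 9600, n_steps = 32))
  f <- tempfile(fileext = ".csv")
  write_sequence_csv(sq, f)
  d <- read.csv(f)
  expect_equal(d$dwell_us, sq$steps$dwell_us)
  side <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  expect_equal(side$exposure_us, 9600)
  expect_true(side$delays_applied)
})

test_that("k-linear sweeps are uniform in k with exact endpoints", {
  p2 <- design_k_linear_sweep(650, 950, 2)
  expect_equal(sort(p2$wavelengths), c(650, 950))
  p3 <- design_k_linear_sweep(650, 950, 3)
  # middle wavelength is the harmonic mean of the band edges
  expect_equal(p3$wavelengths[2], 2 * 650 * 950 / (650 + 950))
  p250 <- design_k_linear_sweep(650, 950, 250)
  dk <- diff(p250$wavenumbers)
  expect_lt(max(abs(dk - mean(dk))) / mean(dk), 1e-12)
  tab <- default_calibration()
  expect_error(design_k_linear_sweep(500, 950, 10, tab), "range")
})

test_that("exposure shaping flattens any positive efficiency profile", {
  tab <- default_calibration()
  plan <- design_exposure_shaping(design_k_linear_sweep(650, 950, 100, tab),
                                  tab)
  eff <- efficiency_at(tab, plan$wavelengths)
  prod <- eff * plan$exposure_weights
  expect_lt(diff(range(prod)) / mean(prod), 1e-9)
  expect_equal(max(plan$exposure_weights), 1)

  # flat efficiency: all weights are 1
  pf <- design_exposure_shaping(design_k_linear_sweep(650, 950, 10),
                                function(lam) rep(1, length(lam)))
  expect_equal(pf$exposure_weights, rep(1, 10))

  # halved efficiency at the edges doubles the edge weights
  ph <- design_exposure_shaping(design_k_linear_sweep(650, 950, 11),
    function(lam) ifelse(lam < 660 | lam > 940, 0.5, 1))
  expect_equal(ph$exposure_weights[c(1, 11)] /
               ph$exposure_weights[6], c(2, 2))

  # random positive profile flattens to 1e-9
  set.seed(21)
  prof <- runif(33, 0.05, 1)
  fn <- function(lam) prof[match(lam, pr33$wavelengths)]
  pr33 <- design_k_linear_sweep(650, 950, 33)
  ps <- design_exposure_shaping(pr33, fn)
  expect_lt(diff(range(prof * ps$exposure_weights)) / mean(prof), 1e-9)

  expect_error(design_exposure_shaping(pr33, function(lam) rep(0, 33)),
               "zero")
})
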
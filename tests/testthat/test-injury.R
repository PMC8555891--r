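test_that("spectrum of synthetic tones finds the right dominant peak", {
  t <- seq(0, 10e-3, by = 1e-6)
  tone <- tibble::tibble(time_s = t, p = sin(2 * pi * 9.7e3 * t))
  sp <- pressure_spectrum(tone)
  bin <- 1 / (4 * 2^ceiling(log2(length(t))) * 1e-6)
  expect_lt(abs(dominant_peak(sp) - 9.7e3), bin)
  two <- tibble::tibble(time_s = t,
                        p = sin(2 * pi * 5e3 * t) +
                            2 * sin(2 * pi * 10e3 * t))
  expect_lt(abs(dominant_peak(pressure_spectrum(two)) - 10e3), bin)
  # amplitude calibration: a unit sinusoid has unit peak amplitude
  expect_equal(max(sp$amplitude), 1, tolerance = 0.05)
})

test_that("non-uniform sampling is refused", {
  bad <- tibble::tibble(time_s = c(0, 1e-6, 3e-6, 7e-6),
                        p = c(0, 1, 0, -1))
  expect_error(pressure_spectrum(bad), class = "hpmwave_error_sampling")
})

test_that("extrema of an explicit field history match the analytic
           minimum of the test signal", {
  times <- seq(0, 1e-3, by = 1e-5)
  f0 <- 3e3; tau <- 3e-4
  fields <- lapply(times, function(t)
    array(exp(-t / tau) * sin(2 * pi * f0 * t) * c(1, -2, 0.5, 3),
          dim = c(2, 2, 1)))
  ex <- extrema_maps(list(times = times, fields = fields))
  env <- exp(-times / tau) * sin(2 * pi * f0 * times)
  # element [2,1,1] carries amplitude -2: its minimum is -2 * max(env)
  expect_equal(ex$min_pressure_map[2, 1, 1], -2 * max(env))
  amps <- c(1, -2, 0.5, 3)
  expect_equal(ex$min_pressure,
               min(vapply(amps, function(a) min(a * env), numeric(1))))
  expect_error(extrema_maps(list(times = numeric(), fields = list())),
               class = "hpmwave_error_domain")
  zero <- extrema_maps(list(times = 0, fields = list(array(0, c(2, 2, 1)))))
  expect_equal(zero$min_pressure, 0)
})

test_that("injury flags follow the packaged thresholds", {
  mk <- function(minp, mps = 0.01, rate = 1)
    assess_injury(list(min_pressure = minp, mps = mps,
                       max_strain_rate = rate))
  a <- mk(-120e3)
  expect_true(a$cavitation_flag)           # within the -100..-150 band
  expect_false(a$strain_flag)              # 1% vs 18%
  expect_identical(a$nfl_band_comparison, "within")
  b <- mk(-50e3)
  expect_false(b$cavitation_flag)
  expect_identical(b$nfl_band_comparison, "within")  # 50 kPa in 20-120
  expect_identical(mk(-5e3)$nfl_band_comparison, "below")
  expect_identical(mk(-300e3)$nfl_band_comparison, "above")
  expect_true(mk(-10e3, mps = 0.2)$strain_flag)
  expect_true(mk(-10e3, mps = 0.04)$strain_flag_high_rate)
  td <- tidy(a)
  expect_equal(nrow(td), 3)
})

test_that("exposure arithmetic reproduces the closed forms", {
  # 8 MW through 40 dBi at 25 m is about a megawatt-class power density
  s <- power_density_at_range(8e6, 40, 25)
  expect_equal(s, 8e6 * 1e4 / (4 * pi * 625) / 10)
  expect_equal(s / 1e6, 1.018, tolerance = 1e-3)
  # isotropic radiator: 4 pi W at 1 m -> 1 W/m^2 = 0.1 mW/cm^2
  expect_equal(power_density_at_range(4 * pi, 0, 1), 0.1)
  expect_equal(power_density_at_range(1, 0, 2),
               power_density_at_range(1, 0, 1) / 4)
  expect_error(power_density_at_range(1, 0, 0),
               class = "hpmwave_error_domain")

  e <- erl_energy(1e9)
  expect_equal(e$erl_W_m2, 5)
  expect_equal(e$energy_J_m2, 9000)
  expect_error(erl_energy(3e9), class = "hpmwave_error_range")

  expect_equal(pulse_energy_density(1.5e7, 5e-6), 75)
  expect_equal(pulse_energy_density(1e6, 0), 0)
})

test_that("dominant frequency is a property of the cavity, not the
           exposure direction", {
  # exact rotational symmetry on the spherical head phantom: +x and +y
  # exposures give identical dominant peaks at the rotated probe
  ph <- build_layered_head(spacing = 3e-3, shape = "sphere",
                           include_ventricles = FALSE)
  wy <- solve_cartesian(ph, synthetic_exposure_load(ph, 0.001, 5e-6,
                                                    direction = "+y"),
                        duration = 2e-3, skull = "stiff_fluid",
                        track_strain = FALSE)
  wx <- solve_cartesian(ph, synthetic_exposure_load(ph, 0.001, 5e-6,
                                                    direction = "+x"),
                        duration = 2e-3, skull = "stiff_fluid",
                        track_strain = FALSE)
  py <- dominant_peak(pressure_spectrum(wy$traces,
                                        probe = "periventricular"))
  px <- dominant_peak(pressure_spectrum(wx$traces,
                                        probe = "periventricular"))
  bin <- 1 / (4 * 2^ceiling(log2(nrow(wy$traces))) *
                diff(wy$traces$time_s[1:2]))
  expect_lt(abs(py - px), bin)

  # on the ellipsoid the shared mode set is direction-invariant: each
  # direction's dominant peak appears as a spectral peak of the other
  phe <- build_layered_head(spacing = 2.5e-3)
  agg <- lapply(c("+y", "+x"), function(dir) {
    w <- solve_cartesian(phe, synthetic_exposure_load(phe, 0.001, 5e-6,
                                                      direction = dir),
                         duration = 3e-3, skull = "stiff_fluid",
                         track_strain = FALSE)
    sps <- lapply(phe$probes$name, function(nm)
      pressure_spectrum(w$traces, probe = nm))
    s <- sps[[1]]
    s$amplitude <- Reduce(`+`, lapply(sps, function(x) x$amplitude))
    s
  })
  bin2 <- diff(agg[[1]]$frequency_Hz[1:2])
  doms <- sapply(agg, function(s) {
    cand <- s$frequency_Hz >= 1e3 & s$frequency_Hz <= 3e4
    s$frequency_Hz[cand][which.max(s$amplitude[cand])]
  })
  expect_lt(min(abs(spectrum_peaks(agg[[2]]) - doms[1])), 1.5 * bin2)
  expect_lt(min(abs(spectrum_peaks(agg[[1]]) - doms[2])), 1.5 * bin2)
  # both dominants sit in the microwave-auditory band
  expect_true(all(doms > 6e3 & doms < 13e3))
})
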
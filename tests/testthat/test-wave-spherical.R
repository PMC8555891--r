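K_brain <- 1040 * 1450^2          # 2.1866e9 Pa

test_that("characteristic time is a / c and scales linearly", {
  tc <- characteristic_time(0.085, 1450)
  expect_equal(tc, 0.085 / 1450)
  expect_equal(tc * 1e6, 58.6, tolerance = 0.01)
  expect_equal(characteristic_time(0, 1450), 0)
  expect_equal(characteristic_time(0.17, 1450), 2 * tc)
  expect_error(characteristic_time(1, -1), class = "hpmwave_error_domain")
})

test_that("inertial-confinement pressure is K beta dT", {
  expect_equal(inertial_confinement_pressure(2.19e9, 3.6e-4, 0.001),
               788.4)
  expect_equal(inertial_confinement_pressure(2.19e9, 3.6e-4, 0), 0)
  expect_equal(inertial_confinement_pressure(2.19e9, 3.6e-4, 0.002),
               2 * inertial_confinement_pressure(2.19e9, 3.6e-4, 0.001))
  expect_error(inertial_confinement_pressure(-1, 3.6e-4, 1),
               class = "hpmwave_error_domain")
})

test_that("no forcing gives an identically zero field", {
  s <- solve_spherical(0.075, delta_T = 0, tau_d = 5e-6, duration = 3e-4)
  expect_equal(max(abs(s$field)), 0)
})

test_that("uniform rapid heating under a rigid boundary holds the
           confinement plateau K beta dT", {
  s <- solve_spherical(0.075, delta_T = 0.001, tau_d = 1e-7,
                       duration = 2e-4, boundary = "rigid",
                       rho = 1040, c_bulk = 1450, beta = 3.6e-4)
  plateau <- K_brain * 3.6e-4 * 0.001
  tr <- s$traces
  late <- tr$p_core_Pa[tr$time_s > 1e-5]
  expect_lt(max(abs(late - plateau)) / plateau, 1e-6)
})

test_that("pressure-release sphere rings at the radial eigenmodes
           n c / (2a)", {
  a <- 0.075
  s <- solve_spherical(a, delta_T = function(r) exp(-(a - r) / 0.025),
                       tau_d = 5e-6, duration = 5e-3,
                       boundary = "pressure_release")
  f1 <- 1450 / (2 * a)                       # 9.667 kHz fundamental
  pk <- dominant_peak(pressure_spectrum(s$traces, probe = "mid"))
  expect_equal(pk, f1, tolerance = 0.01)
  # the centre probe sits on the antinode of every radial mode: its
  # dominant peak is still a multiple of the fundamental
  pk0 <- dominant_peak(pressure_spectrum(s$traces, probe = "core"))
  expect_lt(min(abs(pk0 - f1 * (1:6))) / f1, 0.05)
})

test_that("dominant eigenfrequency converges with shell refinement
           (within 2% at 128 shells)", {
  a <- 0.075; f1 <- 1450 / (2 * a)
  err <- sapply(c(32, 128), function(ns) {
    s <- solve_spherical(a, delta_T = function(r) exp(-(a - r) / 0.025),
                         tau_d = 5e-6, duration = 4e-3, n_shells = ns)
    abs(dominant_peak(pressure_spectrum(s$traces, probe = "mid")) - f1) / f1
  })
  expect_lt(err[2], 0.02)
  expect_lt(err[1], 0.05)
})

test_that("slow heating of an unconfined sphere leaves almost no residual
           stress (compatibility limit)", {
  a <- 0.075
  tc <- characteristic_time(a, 1450)
  scale <- K_brain * 3.6e-4 * 0.001
  for (prof in list(0.001, function(r) 0.001 * r / a)) {
    s <- solve_spherical(a, delta_T = prof, tau_d = 50 * tc,
                         duration = 65 * tc, boundary = "pressure_release")
    expect_lt(s$max_abs_p_post_ramp / scale, 0.05)
  }
})

test_that("pressure scales linearly with the temperature load", {
  a <- 0.05
  s1 <- solve_spherical(a, delta_T = 0.001, tau_d = 5e-6, duration = 2e-4)
  s2 <- solve_spherical(a, delta_T = 0.003, tau_d = 5e-6, duration = 2e-4)
  expect_equal(s2$field, 3 * s1$field, tolerance = 1e-12)
})

test_that("probe radii outside the sphere are refused and energy stays
           bounded long after forcing", {
  expect_error(solve_spherical(0.05, 0.001, 5e-6, 1e-4,
                               probes = c(bad = 0.06)),
               class = "hpmwave_error_domain")
  tc <- characteristic_time(0.05, 1450)
  s <- solve_spherical(0.05, delta_T = 0.001, tau_d = 5e-6,
                       duration = 15 * tc)
  early <- max(abs(s$field[, s$times < 3 * tc]))
  late <- max(abs(s$field[, s$times > 12 * tc]))
  expect_lt(late, 2 * early)
})
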
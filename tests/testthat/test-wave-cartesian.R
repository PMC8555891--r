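sphere_load <- function(ph, peak, tau_d) {
  dT <- array(peak * (ph$labels == 5L), dim = dim(ph$labels))
  hpmwave:::new_temperature_load(dT, tau_d, NA_real_)
}

test_that("zero load propagates nothing", {
  ph <- build_sphere_phantom(0.03, 3e-3, properties = "white")
  w <- solve_cartesian(ph, sphere_load(ph, 0, 5e-6), duration = 1e-4,
                       track_strain = FALSE)
  expect_equal(max(abs(as.matrix(w$traces[, -1]))), 0)
  expect_equal(max(abs(w$min_pressure)), 0)
})

test_that("a symmetric load on a symmetric phantom stays voxel-wise
           mirror symmetric", {
  ph <- build_sphere_phantom(0.05, 2.5e-3, properties = "white")
  w <- solve_cartesian(ph, sphere_load(ph, 0.001, 2e-6), duration = 6e-5,
                       track_strain = FALSE)
  d <- dim(w$p_final)
  for (fld in list(w$p_final, w$min_pressure)) {
    expect_equal(max(abs(fld - fld[d[1]:1, , ])) / max(abs(fld)), 0,
                 tolerance = 1e-10)
    expect_equal(max(abs(fld - fld[, d[2]:1, ])) / max(abs(fld)), 0,
                 tolerance = 1e-10)
  }
})

test_that("3D confinement plateau matches K beta dT within 2%", {
  ph <- build_sphere_phantom(0.05, 2.5e-3, properties = "white")
  w <- solve_cartesian(ph, sphere_load(ph, 0.001, 2e-6), duration = 2.5e-5,
                       track_strain = FALSE, probe_dt = 2e-6)
  plateau <- inertial_confinement_pressure(1040 * 1450^2, 3.6e-4, 0.001)
  tr <- w$traces
  # centre probe before the surface release wave arrives (a/c = 34 us)
  mid <- tr$p_periventricular_Pa[tr$time_s > 4e-6 & tr$time_s < 2.4e-5]
  expect_lt(max(abs(mid - plateau)) / plateau, 0.02)
})

test_that("pressure is exactly linear in the temperature load", {
  ph <- build_sphere_phantom(0.03, 3e-3, properties = "white")
  w1 <- solve_cartesian(ph, sphere_load(ph, 0.001, 5e-6), duration = 1e-4,
                        track_strain = FALSE)
  w2 <- solve_cartesian(ph, sphere_load(ph, 0.005, 5e-6), duration = 1e-4,
                        track_strain = FALSE)
  expect_equal(w2$min_pressure, 5 * w1$min_pressure, tolerance = 1e-9)
})

test_that("stress focusing weakens as the pulse lengthens past tau_c", {
  ph <- build_sphere_phantom(0.05, 2.5e-3, properties = "white")
  tc <- characteristic_time(0.05, 1450)
  peaks <- sapply(c(0.1, 1, 10), function(ratio) {
    tau <- ratio * tc
    w <- solve_cartesian(ph, sphere_load(ph, 0.001, tau),
                         duration = 6 * tc + tau, track_strain = FALSE)
    -min(w$min_pressure)
  })
  expect_true(all(diff(peaks) < 0))
})

test_that("a front-weighted load focuses tension in the deep brain, not at
           the heated surface", {
  ph <- build_layered_head(spacing = 2.5e-3)
  load <- synthetic_exposure_load(ph, 0.001, 5e-6, direction = "+y")
  w <- solve_cartesian(ph, load, duration = 4.5e-4, skull = "stiff_fluid",
                       track_strain = FALSE)
  mp <- w$min_pressure
  fluid <- ph$labels %in% c(3L, 4L, 5L, 6L)
  d <- dim(mp)
  # split the fluid compartment by depth from the irradiated (anterior) side
  jmax <- max(which(apply(array(fluid, d), 2, any)))
  jmin <- min(which(apply(array(fluid, d), 2, any)))
  surf <- array(FALSE, d); deep <- array(FALSE, d)
  surf[, (jmax - 5):jmax, ] <- TRUE
  mid_j <- (jmin + jmax) %/% 2
  deep[, (mid_j - 8):(mid_j + 8), ] <- TRUE
  expect_lt(min(mp[fluid & deep]), min(mp[fluid & surf]))
  # the deep tensile peak is registered at brain probes, strains stay tiny
  expect_lt(min(mp[fluid]), 0)
})

test_that("strain metrics are finite, tiny for millidegree loads, and
           grow with the load", {
  ph <- build_sphere_phantom(0.03, 3e-3, properties = "white")
  w <- solve_cartesian(ph, sphere_load(ph, 0.001, 5e-6), duration = 2e-4,
                       track_strain = TRUE, strain_every = 5L)
  expect_true(all(is.finite(w$strain$mps)))
  expect_gt(w$mps, 0)
  expect_lt(w$mps, 1e-4)
  expect_gt(w$max_strain_rate, 0)
})

test_that("temperature loads must be co-registered", {
  ph <- build_sphere_phantom(0.03, 3e-3, properties = "white")
  bad <- hpmwave:::new_temperature_load(array(0, dim = c(2, 2, 2)), 5e-6, 1)
  expect_error(solve_cartesian(ph, bad, 1e-4),
               class = "hpmwave_error_registration")
})
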
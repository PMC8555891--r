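test_that("tissue table carries the anchored physical constants", {
  tab <- tissue_property_table(1e9)
  expect_silent(validate_tissue_table(tab))
  brain <- tab[tab$name %in% c("gray", "white"), ]
  expect_true(all(brain$c_bulk == 1450))
  expect_equal(tab$alpha[tab$name == "skull"], 0.27e-4)
  expect_equal(tab$beta, 3 * tab$alpha)
  expect_equal(tab$K, tab$rho * tab$c_bulk^2)
  vac <- tissue_property_table(1e9, include_vacuum = TRUE)
  v <- vac[vac$name == "vacuum", ]
  expect_equal(v$eps_r, 1)
  expect_equal(v$sigma, 0)
})

test_that("dielectric lookup interpolates within band and refuses outside", {
  t1 <- tissue_property_table(1e9)
  t2 <- tissue_property_table(2e9)
  tm <- tissue_property_table(1.5e9)
  g <- function(tt, nm, cl) tt[[cl]][tt$name == nm]
  expect_equal(g(tm, "gray", "eps_r"),
               (g(t1, "gray", "eps_r") + g(t2, "gray", "eps_r")) / 2)
  expect_gt(g(t2, "csf", "sigma"), g(t1, "csf", "sigma"))
  expect_error(tissue_property_table(0.1e9), class = "hpmwave_error_range")
  expect_error(tissue_property_table(5e9), class = "hpmwave_error_range")
  # acoustic/thermal columns frequency-independent
  expect_equal(t1[c("rho", "cp", "c_bulk", "beta")],
               t2[c("rho", "cp", "c_bulk", "beta")])
})

test_that("validate_tissue_table enforces positivity and K consistency", {
  tab <- tissue_property_table(1e9)
  bad <- tab; bad$K[2] <- bad$K[2] * 1.001
  expect_error(validate_tissue_table(bad), class = "hpmwave_error_domain")
  bad2 <- tab; bad2$rho[1] <- -1
  expect_error(validate_tissue_table(bad2), class = "hpmwave_error_domain")
})

test_that("layer geometry: 0.17 m cranium with 7 mm skull and 3 mm CSF
           leaves a 0.15 m brain compartment", {
  ph <- build_layered_head(outer_diameter = 0.17,
                           layer_thicknesses = c(skull = 7e-3, csf = 3e-3),
                           spacing = 2e-3, shape = "sphere",
                           include_ventricles = FALSE)
  expect_equal(ph$head_length, 0.17)
  brain <- ph$labels == tissue_labels[["white"]]
  jr <- range(which(apply(brain, 2, any)))
  extent <- (diff(jr) + 1) * ph$spacing
  expect_lt(abs(extent - 0.15), 2 * ph$spacing + 1e-12)
})

test_that("default head phantom has a 0.17 m cranium and valid probes", {
  ph <- build_layered_head(spacing = 2.5e-3)
  expect_equal(ph$head_length, 0.17)
  expect_silent(validate_phantom(ph))
  expect_setequal(ph$probes$name,
                  c("frontal", "periventricular", "occipital"))
  # frontal probe anterior (larger y) of the occipital probe
  pr <- ph$probes
  expect_gt(pr$j[pr$name == "frontal"], pr$j[pr$name == "occipital"])
})

test_that("voxelized sphere volume matches the analytic volume", {
  ph <- build_sphere_phantom(0.05, 2e-3)
  vol <- sum(ph$labels == 5L) * ph$spacing^3
  expect_lt(abs(vol - 4 / 3 * pi * 0.05^3) / (4 / 3 * pi * 0.05^3), 0.05)
  # convergence: finer spacing reduces the error
  err <- sapply(c(4e-3, 2e-3, 1e-3), function(sp) {
    p <- build_sphere_phantom(0.05, sp)
    abs(sum(p$labels == 5L) * sp^3 - 4 / 3 * pi * 0.05^3)
  })
  expect_true(all(diff(err) < 0))
})

test_that("phantom is voxel-wise mirror symmetric about the midsagittal
           plane", {
  ph <- build_layered_head(spacing = 2.5e-3)
  d <- dim(ph$labels)
  expect_identical(ph$labels, ph$labels[d[1]:1, , ])
  sph <- build_sphere_phantom(0.03, 2e-3)
  ds <- dim(sph$labels)
  expect_identical(sph$labels, sph$labels[, ds[2]:1, ])
  expect_identical(sph$labels, sph$labels[, , ds[3]:1])
})

test_that("impossible geometries are refused", {
  expect_error(
    build_layered_head(outer_diameter = 0.04,
                       layer_thicknesses = c(skin = 10e-3, skull = 10e-3,
                                             csf = 5e-3)),
    class = "hpmwave_error_geometry")
  expect_error(
    build_layered_head(spacing = 5e-3),
    class = "hpmwave_error_resolution")
  expect_error(build_sphere_phantom(-1, 1e-3),
               class = "hpmwave_error_domain")
})

test_that("phantom NIfTI + sidecar round trip preserves everything", {
  ph <- build_layered_head(spacing = 4e-3,
                           layer_thicknesses = c(skin = 4e-3, skull = 7e-3,
                                                 csf = 4e-3))
  path <- file.path(tempdir(), "head.nii.gz")
  write_phantom(ph, path)
  ph2 <- read_phantom(path)
  expect_identical(ph2$labels, ph$labels)
  expect_equal(ph2$spacing, ph$spacing)
  expect_equal(ph2$head_length, ph$head_length)
  expect_equal(as.data.frame(ph2$tissue_table),
               as.data.frame(ph$tissue_table))
  expect_equal(as.data.frame(ph2$probes), as.data.frame(ph$probes))
  unlink(c(path, paste0(path, ".json")))
})
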
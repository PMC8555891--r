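#' Plane-wave exposure source
#'
#' Vertically polarized (E parallel to z) plane wave travelling along a
#' horizontal axis, the exposure geometry for frontal (`+y`) and side
#' (`+x`) illumination. The polarization is orthogonal to every supported
#' propagation axis by construction.
#'
#' @param frequency Carrier frequency, Hz.
#' @param amplitude Incident peak electric field, V/m.
#' @param propagation_axis One of `"+x"`, `"-x"`, `"+y"`, `"-y"`.
#' @return An `hpm_source`.
#' @export
plane_wave_source <- function(frequency, amplitude = 100,
                              propagation_axis = "+y") {
  if (frequency <= 0 || amplitude <= 0)
    abort("`frequency` and `amplitude` must be positive.",
          class = "hpmwave_error_domain")
  if (!propagation_axis %in% c("+x", "-x", "+y", "-y"))
    abort("Unsupported propagation axis (vertical incidence not modelled).",
          class = "hpmwave_error_domain")
  structure(list(frequency = frequency, amplitude = amplitude,
                 propagation_axis = propagation_axis, polarization = "z"),
            class = "hpm_source")
}

#' Incident power density of a plane wave in free space
#'
#' `S = E0^2 / (2 eta0)` converted from W/m^2 to mW/cm^2 (factor 10).
#'
#' @param amplitude Peak E-field, V/m.
#' @return Power density, mW/cm^2.
#' @export
incident_power_density <- function(amplitude) {
  amplitude^2 / (2 * .const$eta0) / .const$mwcm2
}

# minimum tissue wavelength (m) at f for a tissue table
.min_wavelength <- function(tab, frequency) {
  w <- 2 * pi * frequency
  n_eff <- Re(sqrt(complex(real = tab$eps_r,
                           imaginary = tab$sigma / (w * .const$eps0))))
  .const$c0 / frequency / max(n_eff, 1)
}

# average a cell-centred array onto edge positions by mean over the 4
# neighbouring cells orthogonal to `axis` (pad with `fill` outside)
.edge_average <- function(a, axis, fill) {
  d <- dim(a)
  pad <- array(fill, dim = d + 1L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- a
  sh <- function(di, dj, dk)
    pad[(2:(d[1] + 1)) - di, (2:(d[2] + 1)) - dj, (2:(d[3] + 1)) - dk]
  if (axis == 1)      (sh(0,0,0) + sh(0,1,0) + sh(0,0,1) + sh(0,1,1)) / 4
  else if (axis == 2) (sh(0,0,0) + sh(1,0,0) + sh(0,0,1) + sh(1,0,1)) / 4
  else                (sh(0,0,0) + sh(1,0,0) + sh(0,1,0) + sh(1,1,0)) / 4
}

#' Run the steady-state FDTD solver
#'
#' Solves Maxwell's equations on the voxel phantom for a plane-wave source
#' and returns the per-voxel RMS electric-field magnitude over the final
#' full carrier cycle. The phantom is embedded in vacuum with a CPML
#' absorbing boundary; the plane wave is injected through the scattered-field
#' formulation (the analytic incident field acts as a volumetric source in
#' non-vacuum voxels), so an empty grid reproduces the incident wave
#' exactly. The run is refused unless the grid resolves at least
#' `cells_per_wavelength` cells per wavelength in the optically densest
#' tissue, and it errors if the cycle-to-cycle RMS drift has not fallen
#' below `tol` within `n_cycles` (a minimum of 20 cycles is always run).
#'
#' @param phantom An `hpm_phantom`.
#' @param source An [plane_wave_source()].
#' @param n_cycles Maximum number of carrier cycles (default 30).
#' @param pml_cells CPML thickness in cells (default 10, polynomial grading
#'   order 3).
#' @param gap_cells Vacuum gap between phantom and CPML.
#' @param tol Steady-state declaration threshold on the relative per-cycle
#'   RMS change (default 0.005).
#' @param cells_per_wavelength Resolution requirement (default 10).
#' @return An `hpm_field`: list with `rms_E` (array, V/m, phantom grid),
#'   `source`, `cycles`, `converged`, `metrics`.
#' @export
run_fdtd <- function(phantom, source, n_cycles = 30, pml_cells = 10,
                     gap_cells = 4, tol = 0.005,
                     cells_per_wavelength = 10) {
  stopifnot(inherits(phantom, "hpm_phantom"), inherits(source, "hpm_source"))
  tab <- phantom$tissue_table
  present <- tab[tab$label %in% unique(as.integer(phantom$labels)), ]
  lam_min <- if (nrow(present)) .min_wavelength(present, source$frequency)
             else .const$c0 / source$frequency
  if (phantom$spacing > lam_min / cells_per_wavelength)
    abort(sprintf(
      paste0("Spacing %.3g m under-resolves the densest tissue: need <= ",
             "%.3g m for %d cells per wavelength."),
      phantom$spacing, lam_min / cells_per_wavelength, cells_per_wavelength),
      class = "hpmwave_error_resolution")
  if (!is.null(phantom$frequency) &&
      abs(phantom$frequency - source$frequency) >
        1e-6 * source$frequency)
    warn("Phantom tissue table was evaluated at a different frequency.")

  dx <- phantom$spacing
  m <- pml_cells + gap_cells
  d0 <- dim(phantom$labels)
  dims <- d0 + 2L * m
  labels <- array(0L, dim = dims)
  labels[m + seq_len(d0[1]), m + seq_len(d0[2]), m + seq_len(d0[3])] <-
    phantom$labels

  lut <- function(col, fill) {
    l <- rep(fill, max(tab$label) + 1L); l[tab$label + 1L] <- tab[[col]]
    array(l[labels + 1L], dim = dims)
  }
  eps_cell <- lut("eps_r", 1) * .const$eps0
  sig_cell <- lut("sigma", 0)

  dt_cfl <- 0.95 * dx / (.const$c0 * sqrt(3))
  period <- 1 / source$frequency
  spc <- as.integer(ceiling(period / dt_cfl))
  dt <- period / spc

  coefs <- function(axis) {
    e <- .edge_average(eps_cell, axis, .const$eps0)
    s <- .edge_average(sig_cell, axis, 0)
    den <- 1 + s * dt / (2 * e)
    list(ca = (1 - s * dt / (2 * e)) / den, cb = (dt / e) / den,
         eps = e, sig = s)
  }
  cx <- coefs(1); cy <- coefs(2); cz <- coefs(3)
  srcA <- cz$eps - .const$eps0
  srcSig <- cz$sig

  ax <- source$propagation_axis
  prop_axis <- if (ax %in% c("+x", "-x")) 0L else 1L
  prop_sign <- if (ax %in% c("+x", "+y")) 1L else -1L

  res <- .fdtd_core(cx$ca, cx$cb, cy$ca, cy$cb, cz$ca, cz$cb,
                    srcA, srcSig,
                    as.integer(dims), dx, dt,
                    source$frequency, source$amplitude,
                    prop_axis, prop_sign,
                    as.integer(pml_cells), 3.0, 0.05,
                    spc, min(20L, as.integer(n_cycles)),
                    as.integer(n_cycles), tol, 3.0)
  if (!res$converged)
    abort(sprintf(
      "FDTD failed to reach steady state within %d cycles (last drift %.3g).",
      n_cycles, {
        mm <- res$metrics; n <- length(mm)
        if (n >= 2) abs(mm[n] - mm[n - 1]) / max(mm[n], 1e-300) else NA_real_
      }), class = "hpmwave_error_convergence")

  to_arr <- function(v) array(v, dim = dims)
  SEx <- to_arr(res$SEx); SEy <- to_arr(res$SEy); SEz <- to_arr(res$SEz)
  # interpolate node mean-squares to cell centres
  n1 <- dims[1]; n2 <- dims[2]; n3 <- dims[3]
  i1 <- 1:(n1 - 1); j1 <- 1:(n2 - 1); k1 <- 1:(n3 - 1)
  msq <- array(0, dim = dims)
  msq[, j1, k1] <- (SEx[, j1, k1] + SEx[, j1 + 1, k1] +
                    SEx[, j1, k1 + 1] + SEx[, j1 + 1, k1 + 1]) / 4
  msq[i1, , k1] <- msq[i1, , k1] +
    (SEy[i1, , k1] + SEy[i1 + 1, , k1] +
     SEy[i1, , k1 + 1] + SEy[i1 + 1, , k1 + 1]) / 4
  msq[i1, j1, ] <- msq[i1, j1, ] +
    (SEz[i1, j1, ] + SEz[i1 + 1, j1, ] +
     SEz[i1, j1 + 1, ] + SEz[i1 + 1, j1 + 1, ]) / 4
  rms <- sqrt(msq)
  crop <- rms[m + seq_len(d0[1]), m + seq_len(d0[2]), m + seq_len(d0[3])]
  structure(list(rms_E = crop, source = source, cycles = res$cycles,
                 converged = res$converged, metrics = res$metrics,
                 dt = dt, steps_per_cycle = spc),
            class = "hpm_field")
}
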
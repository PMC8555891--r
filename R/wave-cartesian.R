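#' @title 3D Cartesian thermoelastic pressure-wave solver
#' @name wave_cartesian
NULL

.fluid_labels <- c(3L, 4L, 5L, 6L)   # csf, gray, white, ventricle

#' 3D thermoelastic pressure-wave solve on a voxel phantom
#'
#' Staggered pressure-velocity leapfrog solve of the linear acoustic
#' equations with heterogeneous density and bulk modulus and thermoelastic
#' forcing from the linear heating ramp. Brain tissue, CSF and ventricles
#' are fluid-like; the skull is by default a rigid boundary (zero normal
#' velocity), optionally a stiff non-expanding fluid with cortical-bone
#' density and wave speed. Skin and everything outside the cranium are
#' mechanically excluded. Fluid voxels facing vacuum (e.g. a bare sphere
#' phantom) form a free, pressure-release surface. Displacement is
#' integrated alongside velocity and the maximum principal logarithmic
#' strain and principal strain rate are tracked over gray/white matter.
#'
#' @param phantom An `hpm_phantom` at the wave-grid resolution.
#' @param load An `hpm_templ` co-registered with the phantom.
#' @param duration Simulated time, s.
#' @param probes Probe tibble (`name`, `i`, `j`, `k`); default the
#'   phantom's probes.
#' @param skull `"rigid"` or `"stiff_fluid"`.
#' @param cfl Fraction of the 3D stability bound (default 0.9).
#' @param probe_dt Target trace sampling interval, s.
#' @param track_strain Integrate displacement and evaluate strain metrics.
#' @param strain_every Strain evaluation stride in solver steps.
#' @return An `hpm_wave`: `traces` (wide tibble `time_s`, `p_<probe>_Pa`),
#'   `min_pressure` (per-voxel minimum-over-time array, Pa), `strain`
#'   (tibble `time_s`, `mps`, `strain_rate`), `mps`, `max_strain_rate`,
#'   `dt`, and run parameters.
#' @export
solve_cartesian <- function(phantom, load, duration,
                            probes = NULL,
                            skull = c("rigid", "stiff_fluid"),
                            cfl = 0.9, probe_dt = 1e-6,
                            track_strain = TRUE, strain_every = 10L) {
  skull <- match.arg(skull)
  stopifnot(inherits(phantom, "hpm_phantom"), inherits(load, "hpm_templ"))
  d <- dim(phantom$labels)
  if (!identical(dim(load$delta_T), d))
    abort("Temperature load not co-registered with the phantom.",
          class = "hpmwave_error_registration")
  dx <- phantom$spacing
  labs <- phantom$labels

  fluid <- array(labs %in% .fluid_labels, dim = d)
  rigid <- array(FALSE, dim = d)
  if (any(labs == 2L)) {
    if (skull == "rigid") rigid <- labs == 2L else fluid <- fluid | labs == 2L
  }
  rho <- .voxel_property(phantom, "rho", fill = 0)
  K <- .voxel_property(phantom, "K", fill = 0)
  beta <- .voxel_property(phantom, "beta", fill = 0)
  beta[labs == 2L] <- 0                    # bone expansion mechanically inert
  K[!fluid] <- 0

  cvals <- sqrt(K[fluid] / rho[fluid])
  cmax <- max(cvals)
  zvals <- sqrt(K[fluid] * rho[fluid])
  if (max(zvals) / min(zvals) > 100)
    warn("Acoustic impedance contrast exceeds 100; expect stiff coupling.")
  dt <- cfl * dx / (cmax * sqrt(3))
  nsteps <- as.integer(ceiling(duration / dt))

  # face inverse densities; 0 encodes a blocked (rigid/vacuum) face
  irho_axis <- function(axis) {
    shift <- function(a) {
      out <- array(0, dim = d)
      if (axis == 1) out[1:(d[1] - 1), , ] <- a[2:d[1], , ]
      if (axis == 2) out[, 1:(d[2] - 1), ] <- a[, 2:d[2], ]
      if (axis == 3) out[, , 1:(d[3] - 1)] <- a[, , 2:d[3]]
      out
    }
    f2 <- shift(fluid); r2 <- shift(rigid); rho2 <- shift(rho)
    out <- array(0, dim = d)
    both <- fluid & f2
    out[both] <- 2 / (rho[both] + rho2[both])
    free1 <- fluid & !f2 & !r2            # this cell fluid, neighbour vacuum
    out[free1] <- 2 / rho[free1]
    free2 <- !fluid & !rigid & f2         # neighbour fluid, this vacuum
    out[free2] <- 2 / rho2[free2]
    out
  }
  irx <- irho_axis(1); iry <- irho_axis(2); irz <- irho_axis(3)

  forc <- K * beta * load$delta_T
  if (is.null(probes)) probes <- phantom$probes
  pidx <- as.integer((probes$i - 1) + d[1] * ((probes$j - 1) +
                                              d[2] * (probes$k - 1)))
  probe_every <- max(1L, as.integer(floor(probe_dt / dt)))
  mask <- as.integer(labs == 4L | labs == 5L)

  res <- .acoustic_core(as.numeric(K), as.numeric(forc),
                        as.numeric(irx), as.numeric(iry), as.numeric(irz),
                        mask, as.integer(d), dx, dt, load$tau_d, nsteps,
                        pidx, probe_every, as.integer(strain_every),
                        isTRUE(track_strain))
  nrec <- res$nrec
  traces <- tibble::tibble(time_s = res$ptimes[seq_len(nrec)])
  for (q in seq_len(nrow(probes)))
    traces[[paste0("p_", probes$name[q], "_Pa")]] <-
      res$ptrace[seq_len(nrec), q]
  strain <- tibble::tibble(time_s = res$strain_times,
                           mps = res$mps, strain_rate = res$strain_rate)
  structure(list(
    traces = traces,
    min_pressure = array(res$minp, dim = d),
    strain = strain,
    mps = if (nrow(strain)) max(strain$mps) else NA_real_,
    max_strain_rate = if (nrow(strain)) max(strain$strain_rate) else NA_real_,
    p_final = array(res$p_final, dim = d),
    dt = dt, duration = duration, skull = skull, tau_d = load$tau_d,
    spacing = dx, labels = labs, probes = probes),
    class = c("hpm_wave", "hpm_waveresult"))
}

#' @export
print.hpm_wave <- function(x, ...) {
  cat(sprintf(
    "<hpm_wave> %s voxels, dt %.3g us, %.3g ms simulated (skull: %s)\n",
    paste(dim(x$min_pressure), collapse = "x"), x$dt * 1e6,
    x$duration * 1e3, x$skull))
  cat(sprintf("  min pressure %.4g kPa, MPS %.3g, max strain rate %.3g /s\n",
              min(x$min_pressure) / 1e3, x$mps, x$max_strain_rate))
  invisible(x)
}

#' Tidy probe traces
#'
#' Long-format probe pressure histories from any wave-solver result.
#'
#' @param x An `hpm_wave` or `hpm_spherical`.
#' @param ... Unused.
#' @return Tibble with `time_s`, `probe`, `pressure_Pa`.
#' @export
tidy.hpm_waveresult <- function(x, ...) {
  tr <- x$traces
  cols <- setdiff(names(tr), "time_s")
  dplyr::bind_rows(lapply(cols, function(cl) {
    tibble::tibble(time_s = tr$time_s,
                   probe = sub("^p_(.*)_Pa$", "\\1", cl),
                   pressure_Pa = tr[[cl]])
  }))
}

#' One-line summary of a wave solve
#'
#' @param x An `hpm_wave`.
#' @param ... Unused.
#' @return One-row tibble: global minimum pressure, MPS, max strain rate,
#'   duration and step.
#' @export
glance.hpm_wave <- function(x, ...) {
  tibble::tibble(min_pressure_Pa = min(x$min_pressure),
                 mps = x$mps, max_strain_rate = x$max_strain_rate,
                 duration_s = x$duration, dt_s = x$dt)
}

#' Plot probe pressure histories
#'
#' @param object An `hpm_wave` or `hpm_spherical`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hpm_waveresult <- function(object, ...) {
  df <- tidy.hpm_waveresult(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s * 1e6,
                                   y = .data$pressure_Pa / 1e3,
                                   colour = .data$probe)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (us)", y = "pressure (kPa)", colour = "probe")
}
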
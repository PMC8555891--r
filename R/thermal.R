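#' @title Adiabatic pulse heating
#' @description Conversion of normalized SAR to the temperature rise at the
#'   end of a single microwave pulse, assuming no thermal diffusion over
#'   the pulse (valid for pulse durations well under 1 ms), and the linear
#'   heating ramp that drives the mechanical solvers.
#' @name thermal
NULL

new_temperature_load <- function(delta_T, tau_d, pin) {
  structure(list(delta_T = delta_T, tau_d = tau_d, pin = pin),
            class = "hpm_templ")
}

#' @export
print.hpm_templ <- function(x, ...) {
  cat(sprintf(
    "<hpm_templ> peak dT %.4g degC, tau_d %.3g s, PIN %.4g mW/cm^2\n",
    max(x$delta_T), x$tau_d, x$pin))
  invisible(x)
}

#' Pulse-end temperature rise from normalized SAR
#'
#' `dT = PIN * SAR* * tau_d / cp` per voxel, the adiabatic limit of the
#' heat equation for a single pulse: absorbed power density divided by the
#' volumetric heat capacity, integrated over the pulse. The temperature
#' rise is exactly linear in both `pin` and `tau_d`.
#'
#' @param sar_map An `hpm_sar` with `sar_star` filled (see
#'   [normalize_sar()]).
#' @param phantom The phantom (supplies per-voxel heat capacity).
#' @param pin Applied incident power density, mW/cm^2 (> 0).
#' @param tau_d Pulse duration, s; a warning is issued at or above 1 ms
#'   where the adiabatic assumption degrades.
#' @return An `hpm_templ` with per-voxel `delta_T` (degC).
#' @export
temperature_rise <- function(sar_map, phantom, pin, tau_d) {
  stopifnot(inherits(sar_map, "hpm_sar"))
  if (is.null(sar_map$sar_star))
    abort("SAR map lacks `sar_star`; call normalize_sar() first.",
          class = "hpmwave_error_domain")
  if (!is.numeric(pin) || length(pin) != 1 || pin <= 0)
    abort("`pin` must be positive (mW/cm^2).", class = "hpmwave_error_domain")
  if (tau_d <= 0)
    abort("`tau_d` must be positive.", class = "hpmwave_error_domain")
  if (tau_d >= 1e-3)
    warn(paste("Pulse duration >= 1 ms: thermal diffusion is no longer",
               "negligible; the adiabatic temperature rise is an upper",
               "bound."))
  cp <- .voxel_property(phantom, "cp", fill = 0)
  dT <- array(0, dim = dim(sar_map$sar_star))
  ok <- cp > 0
  dT[ok] <- pin * sar_map$sar_star[ok] * tau_d / cp[ok]
  new_temperature_load(dT, tau_d, pin)
}

#' Linear heating ramp
#'
#' Temperature at time `t`: a linear ramp reaching `delta_T` at `t =
#' tau_d`, held constant afterwards (thermal conduction is slow compared
#' with the acoustic time scales, so the end-of-pulse field persists over
#' the simulated window).
#'
#' @param load An `hpm_templ`.
#' @param t Time, s (scalar, >= 0).
#' @return Per-voxel temperature array at `t` (degC).
#' @export
ramp_schedule <- function(load, t) {
  stopifnot(inherits(load, "hpm_templ"), t >= 0)
  load$delta_T * min(t / load$tau_d, 1)
}

#' Thermal-diffusion negligibility ratio
#'
#' Ratio of the diffusion length `sqrt(4 D tau_d)` (brain thermal
#' diffusivity `D = 2e-7 m^2/s`) to the heated feature size; values much
#' below 1 justify the adiabatic single-pulse model.
#'
#' @param tau_d Pulse duration, s.
#' @param length_scale Heated feature size, m.
#' @param diffusivity Thermal diffusivity, m^2/s.
#' @return Dimensionless ratio.
#' @export
diffusion_negligibility <- function(tau_d, length_scale,
                                    diffusivity = 2e-7) {
  if (tau_d < 0 || length_scale <= 0)
    abort("Inputs must be positive.", class = "hpmwave_error_domain")
  sqrt(4 * diffusivity * tau_d) / length_scale
}

#' Synthetic front-weighted exposure load
#'
#' An analytic stand-in for a microwave-deposited temperature field: the
#' pulse-end rise decays exponentially with depth from the irradiated
#' surface of the fluid (brain/CSF) compartment, emulating the penetration
#' of the absorbed power, and is zero outside fluid tissues. Useful for
#' exercising the wave solvers without an EM run.
#'
#' @param phantom An `hpm_phantom`.
#' @param peak_dT Temperature rise at the irradiated surface, degC.
#' @param tau_d Pulse duration, s.
#' @param penetration e-folding depth of the deposition, m (default 2.5 cm,
#'   typical of ~1 GHz energy penetration in brain).
#' @param direction Axis the exposure arrives from (`"+y"` frontal: decay
#'   from the anterior surface; `"+x"` side: decay from the +x surface;
#'   and their negatives).
#' @return An `hpm_templ`.
#' @export
synthetic_exposure_load <- function(phantom, peak_dT, tau_d,
                                    penetration = 0.025,
                                    direction = "+y") {
  stopifnot(inherits(phantom, "hpm_phantom"))
  d <- dim(phantom$labels)
  fluid <- array(phantom$labels %in% c(3L, 4L, 5L, 6L), dim = d)
  ax <- switch(direction, "+x" = 1, "-x" = 1, "+y" = 2, "-y" = 2,
               abort("Unsupported direction.", class = "hpmwave_error_domain"))
  pos <- (seq_len(d[ax]) - 0.5) * phantom$spacing
  occ <- apply(fluid, ax, any)
  surf <- if (direction %in% c("+x", "+y")) max(pos[occ]) else min(pos[occ])
  depth <- abs(surf - pos)
  w <- exp(-depth / penetration)
  dT <- array(0, dim = d)
  for (k in seq_len(d[3]))
    dT[, , k] <- if (ax == 1) matrix(w, d[1], d[2])
                 else matrix(w, d[1], d[2], byrow = TRUE)
  dT <- dT * fluid * peak_dT
  new_temperature_load(dT, tau_d, NA_real_)
}
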
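#' @title Spherically symmetric thermoelastic solver
#' @name wave_spherical
NULL

#' Characteristic acoustic time of a sphere
#'
#' `tau_c = a / c_bulk`: the time for a bulk pressure wave to cross the
#' radius. The ratio of pulse duration to this time controls the strength
#' of thermoelastic stress focusing; for the head (`a = 0.085 m`,
#' `c = 1450 m/s`) it is about 59 microseconds.
#'
#' @param a Radius, m (>= 0).
#' @param c_bulk Bulk wave speed, m/s (> 0).
#' @return Characteristic time, s.
#' @export
characteristic_time <- function(a, c_bulk) {
  if (a < 0 || c_bulk <= 0)
    abort("`a` must be >= 0 and `c_bulk` > 0.",
          class = "hpmwave_error_domain")
  a / c_bulk
}

#' Inertial-confinement (instantaneous-heating) stress
#'
#' In the limit of a pulse much shorter than the acoustic transit time the
#' heated material cannot expand, and the induced stress magnitude is
#' `K * beta * dT` (the fluid reduction of `sigma = -C alpha dT`).
#'
#' @param K Bulk modulus, Pa.
#' @param beta Volumetric thermal expansion coefficient, 1/degC.
#' @param delta_T Temperature rise, degC.
#' @return Pressure, Pa.
#' @export
inertial_confinement_pressure <- function(K, beta, delta_T) {
  if (any(K <= 0) || any(beta <= 0))
    abort("`K` and `beta` must be positive.", class = "hpmwave_error_domain")
  K * beta * delta_T
}

#' Spherically symmetric thermoelastic pressure-wave solve
#'
#' Staggered-grid leapfrog integration of the linear acoustic equations
#' with thermoelastic forcing in spherical symmetry:
#' `dp/dt = -K div(v) + K beta dT/dt`, `rho dv/dt = -dp/dr`,
#' with `v(0) = 0` at the (singularity-safe, finite-volume) origin and
#' either a pressure-release or rigid outer boundary. The temperature
#' follows the linear ramp of duration `tau_d` and is held afterwards.
#'
#' @param radius Sphere radius, m.
#' @param delta_T Final temperature rise: scalar, per-shell vector, or a
#'   function of radius (m) returning degC.
#' @param tau_d Heating ramp duration, s.
#' @param duration Simulated time, s (>= 4 tau_c recommended).
#' @param n_shells Number of radial cells (default 256).
#' @param rho,c_bulk,beta Medium properties: scalars or per-shell vectors
#'   (density kg/m^3, bulk wave speed m/s, volumetric expansion 1/degC).
#' @param boundary `"pressure_release"` (free surface) or `"rigid"`.
#' @param probes Named radii (m) at which pressure traces are recorded;
#'   default centre and half-radius.
#' @param cfl Fraction of the stability bound used for the time step.
#' @param probe_dt Target trace sampling interval, s (never finer than the
#'   solver step).
#' @return An `hpm_spherical`: `traces` (wide tibble, `time_s` then one
#'   `p_<name>_Pa` column per probe), `field` (shells x samples pressure
#'   matrix), `r` (shell centres), `times`, `dt`, `max_abs_p_post_ramp`,
#'   and the run parameters.
#' @export
solve_spherical <- function(radius, delta_T, tau_d, duration,
                            n_shells = 256, rho = 1040, c_bulk = 1450,
                            beta = 3.6e-4,
                            boundary = c("pressure_release", "rigid"),
                            probes = NULL, cfl = 0.9, probe_dt = 1e-6) {
  boundary <- match.arg(boundary)
  n <- as.integer(n_shells)
  dr <- radius / n
  r_face <- (0:n) * dr
  r_cent <- ((1:n) - 0.5) * dr
  expand <- function(x) if (length(x) == 1) rep(x, n) else {
    stopifnot(length(x) == n); x }
  rho <- expand(rho); c_bulk <- expand(c_bulk); beta <- expand(beta)
  K <- rho * c_bulk^2
  dT <- if (is.function(delta_T)) delta_T(r_cent) else expand(delta_T)

  dt <- cfl * dr / max(c_bulk)
  if (dt <= 0) abort("Empty grid.", class = "hpmwave_error_domain")
  nsteps <- as.integer(ceiling(duration / dt))
  rec_every <- max(1L, floor(probe_dt / dt))

  if (is.null(probes)) probes <- c(core = r_cent[1], mid = radius / 2)
  pidx <- vapply(probes, function(rr) {
    if (rr < 0 || rr > radius)
      abort("Probe outside the sphere.", class = "hpmwave_error_domain")
    which.min(abs(r_cent - rr))
  }, integer(1))

  # finite-volume divergence weights: (r+^2 v+ - r-^2 v-) * 3/(r+^3 - r-^3)
  w_hi <- 3 * r_face[-1]^2 / (r_face[-1]^3 - r_face[-(n + 1)]^3)
  w_lo <- 3 * r_face[-(n + 1)]^2 / (r_face[-1]^3 - r_face[-(n + 1)]^3)
  rho_face <- (rho[-1] + rho[-n]) / 2       # interior faces 2..n

  p <- numeric(n); v <- numeric(n + 1)
  nrec <- length(seq(rec_every, nsteps, by = rec_every))
  field <- matrix(0, n, nrec)
  times <- numeric(nrec)
  irec <- 0L
  max_post <- 0
  forc <- K * beta * dT

  for (s in seq_len(nsteps)) {
    t0 <- (s - 1) * dt; t1 <- s * dt
    f <- if (t0 < tau_d) (min(t1, tau_d) - t0) / tau_d else 0
    divv <- w_hi * v[-1] - w_lo * v[-(n + 1)]
    p <- p - dt * K * divv + f * forc
    dpdr <- (p[-1] - p[-n]) / dr
    v[2:n] <- v[2:n] - dt / rho_face * dpdr
    if (boundary == "pressure_release") {
      v[n + 1] <- v[n + 1] + dt / rho[n] * 2 * p[n] / dr
    } # rigid: v[n+1] stays 0
    if (t1 > tau_d) max_post <- max(max_post, max(abs(p)))
    if (s %% rec_every == 0) {
      irec <- irec + 1L
      field[, irec] <- p
      times[irec] <- t1
    }
  }
  field <- field[, seq_len(irec), drop = FALSE]
  times <- times[seq_len(irec)]
  traces <- tibble::tibble(time_s = times)
  for (nm in names(pidx))
    traces[[paste0("p_", nm, "_Pa")]] <- field[pidx[nm], ]
  structure(list(traces = traces, field = field, r = r_cent, times = times,
                 dt = dt, boundary = boundary, tau_d = tau_d,
                 radius = radius, c_bulk = c_bulk, rho = rho, beta = beta,
                 K = K, delta_T = dT,
                 max_abs_p_post_ramp = max_post),
            class = c("hpm_spherical", "hpm_waveresult"))
}

#' @export
print.hpm_spherical <- function(x, ...) {
  cat(sprintf(
    "<hpm_spherical> a = %.3g m, %d shells, %d samples to %.3g ms (%s)\n",
    x$radius, length(x$r), length(x$times), max(x$times) * 1e3, x$boundary))
  invisible(x)
}
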
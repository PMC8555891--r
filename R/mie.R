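#' @title Mie-series reference fields
#' @description Analytic electromagnetic fields for a homogeneous
#'   (possibly lossy) dielectric sphere in vacuum illuminated by a linearly
#'   polarized plane wave — the validation oracle for the FDTD solver.
#'   Conventions follow the standard exp(-i omega t) phasor treatment;
#'   peak incident amplitude E0, so RMS magnitudes are |E|/sqrt(2).
#' @name mie
NULL

# spherical Bessel j_0..j_nmax at (possibly complex) z, downward recurrence
.sph_jn <- function(nmax, z) {
  if (abs(z) < 1e-6) {
    # small-argument series j_n ~ z^n / (2n+1)!!
    n <- 0:nmax
    dfact <- cumprod(c(1, 2 * n[-1] + 1))
    return(z^n / dfact * (1 - z^2 / (2 * (2 * n + 3))))
  }
  nstart <- nmax + 15L + as.integer(ceiling(1.2 * abs(z)))
  jp <- 0 + 0i; jc <- 1e-30 + 0i
  out <- complex(nmax + 1L)
  for (n in nstart:1) {
    jm <- (2 * n + 1) / z * jc - jp
    if (n - 1 <= nmax) out[n] <- jm
    jp <- jc; jc <- jm
    # rescale to avoid overflow
    if (Mod(jc) > 1e250) {
      jc <- jc * 1e-250; jp <- jp * 1e-250
      out <- out * 1e-250
    }
  }
  out * (sin(z) / z) / out[1]
}

# spherical Bessel y_n (real or complex z, upward recurrence; |z| not tiny)
.sph_yn <- function(nmax, z) {
  out <- complex(nmax + 1L)
  out[1] <- -cos(z) / z
  if (nmax >= 1) out[2] <- -cos(z) / z^2 - sin(z) / z
  if (nmax >= 2)
    for (n in 2:nmax) out[n + 1] <- (2 * n - 1) / z * out[n] - out[n - 1]
  out
}

#' Mie expansion coefficients
#'
#' Scattering (`a`, `b`) and interior (`c`, `d`) coefficients for a
#' homogeneous sphere of complex refractive index `m` and size parameter
#' `x = k a`, to order `nmax`.
#'
#' @param m Complex refractive index relative to vacuum.
#' @param x Size parameter `k * radius` (dimensionless).
#' @param nmax Series truncation order; default per Wiscombe's criterion
#'   with a floor of `x + 10`.
#' @return List with complex vectors `a`, `b`, `c`, `d` of length `nmax`.
#' @export
mie_coefficients <- function(m, x, nmax = NULL) {
  if (is.null(nmax))
    nmax <- as.integer(ceiling(max(x + 4 * x^(1 / 3) + 2, x + 10)))
  n <- seq_len(nmax)
  jx <- .sph_jn(nmax, x + 0i); yx <- .sph_yn(nmax, x + 0i)
  jmx <- .sph_jn(nmax, m * x)
  psi  <- x * jx;  chi <- -x * yx;  xi <- psi - 1i * chi
  psim <- m * x * jmx
  # derivatives via psi_n' = psi_{n-1} - n/x psi_n (same for chi, xi, psim)
  dpsi  <- psi[n] - n / x * psi[n + 1]
  dxi   <- xi[n] - n / x * xi[n + 1]
  dpsim <- psim[n] - n / (m * x) * psim[n + 1]
  psi_n <- psi[n + 1]; xi_n <- xi[n + 1]; psim_n <- psim[n + 1]

  a <- (m * psim_n * dpsi - psi_n * dpsim) /
       (m * psim_n * dxi - xi_n * dpsim)
  b <- (psim_n * dpsi - m * psi_n * dpsim) /
       (psim_n * dxi - m * xi_n * dpsim)
  c <- (m * psi_n * dxi - m * xi_n * dpsi) /
       (psim_n * dxi - m * xi_n * dpsim)
  d <- (m * psi_n * dxi - m * xi_n * dpsi) /
       (m * psim_n * dxi - xi_n * dpsim)

  mx <- max(Mod(a) + Mod(b))
  if (mx > 0 && (Mod(a[nmax]) + Mod(b[nmax])) / mx > 1e-8)
    abort("Mie series not converged at requested truncation order.",
          class = "hpmwave_error_truncation")
  list(a = a, b = b, c = c, d = d, nmax = nmax)
}

#' Mie efficiencies (extinction, scattering)
#'
#' For a lossless sphere the optical theorem demands `Qext == Qsca`; the
#' test suite uses this as an internal-consistency check of the series.
#'
#' @inheritParams mie_coefficients
#' @return List with `Qext`, `Qsca`.
#' @export
mie_efficiencies <- function(m, x, nmax = NULL) {
  co <- mie_coefficients(m, x, nmax)
  n <- seq_along(co$a)
  list(
    Qext = 2 / x^2 * sum((2 * n + 1) * Re(co$a + co$b)),
    Qsca = 2 / x^2 * sum((2 * n + 1) * (Mod(co$a)^2 + Mod(co$b)^2))
  )
}

# angular functions pi_n, tau_n at mu = cos(theta), orders 1..nmax
.mie_pitau <- function(nmax, mu) {
  p <- numeric(nmax); t <- numeric(nmax)
  p[1] <- 1; t[1] <- mu
  if (nmax >= 2) {
    p[2] <- 3 * mu
    t[2] <- 2 * mu * p[2] - 3 * p[1]
    if (nmax >= 3) for (n in 3:nmax) {
      p[n] <- ((2 * n - 1) * mu * p[n - 1] - n * p[n - 2]) / (n - 1)
      t[n] <- n * mu * p[n] - (n + 1) * p[n - 1]
    }
  }
  list(pi = p, tau = t)
}

#' Analytic plane-wave field of a homogeneous sphere (Mie series)
#'
#' Complex electric-field phasors at arbitrary points, inside (interior
#' expansion, complex permittivity `eps_r - i sigma/(omega eps0)`) and
#' outside (incident + scattered expansion) a homogeneous sphere centred at
#' `centre`. With `eps_r = 1, sigma = 0` the result is the incident plane
#' wave everywhere.
#'
#' @param radius Sphere radius, m.
#' @param eps_r,sigma Sphere relative permittivity and conductivity (S/m).
#' @param source A [plane_wave_source()].
#' @param points N x 3 matrix of lab-frame coordinates (m).
#' @param centre Sphere centre, length-3 (m); default origin.
#' @return N x 3 complex matrix of E-field phasors (lab frame, peak
#'   amplitude convention).
#' @export
mie_reference <- function(radius, eps_r, sigma, source, points,
                          centre = c(0, 0, 0)) {
  stopifnot(is.matrix(points), ncol(points) == 3)
  f <- source$frequency; E0 <- source$amplitude
  w <- 2 * pi * f
  k <- w / .const$c0
  # exp(-i w t) convention: eps_c = eps_r + i sigma/(w eps0), Im(m) >= 0
  m <- sqrt(complex(real = eps_r, imaginary = sigma / (w * .const$eps0)))
  if (Im(m) < 0) m <- -m
  x <- k * radius
  co <- mie_coefficients(m, x)
  nmax <- co$nmax
  nn <- seq_len(nmax)
  En <- (1i)^nn * (2 * nn + 1) / (nn * (nn + 1)) * E0

  # lab -> canonical frame (prop = +z_c, polarization = +x_c)
  ax <- source$propagation_axis
  p_hat <- switch(ax, "+x" = c(1, 0, 0), "-x" = c(-1, 0, 0),
                  "+y" = c(0, 1, 0), "-y" = c(0, -1, 0))
  x_c <- c(0, 0, 1)                       # vertical (z) polarization
  z_c <- p_hat
  y_c <- c(z_c[2] * x_c[3] - z_c[3] * x_c[2],
           z_c[3] * x_c[1] - z_c[1] * x_c[3],
           z_c[1] * x_c[2] - z_c[2] * x_c[1])
  R <- rbind(x_c, y_c, z_c)               # lab vector -> canonical coords

  pts <- sweep(points, 2, centre) %*% t(R)
  out_c <- matrix(0 + 0i, nrow(points), 3)

  r <- sqrt(rowSums(pts^2))
  r <- pmax(r, 1e-9 * radius)
  ct <- pts[, 3] / r
  st <- sqrt(pmax(0, 1 - ct^2))
  phi <- atan2(pts[, 2], pts[, 1])
  cp <- cos(phi); sp <- sin(phi)

  inside <- r <= radius
  for (ii in seq_len(nrow(pts))) {
    pt <- .mie_pitau(nmax, ct[ii])
    if (inside[ii]) {
      rho <- m * k * r[ii]
      j <- .sph_jn(nmax, rho)
      jn <- j[nn + 1]
      Dn <- j[nn] - nn / rho * jn          # [rho j]'/rho = j_{n-1} - n j_n/rho
      Er <- sum(En * (-1i * co$d) * nn * (nn + 1) * pt$pi * st[ii] * jn / rho)
      Et <- sum(En * (co$c * pt$pi * jn - 1i * co$d * pt$tau * Dn))
      Ef <- sum(En * (-co$c * pt$tau * jn + 1i * co$d * pt$pi * Dn))
      Er <- Er * cp[ii]; Et <- Et * cp[ii]; Ef <- Ef * sp[ii]
      Ec <- c(Er, Et, Ef)
    } else {
      rho <- k * r[ii]
      j <- .sph_jn(nmax, rho + 0i); y <- .sph_yn(nmax, rho + 0i)
      h <- j + 1i * y
      hn <- h[nn + 1]
      Dh <- h[nn] - nn / rho * hn
      Er <- sum(En * 1i * co$a * nn * (nn + 1) * pt$pi * st[ii] * hn / rho)
      Et <- sum(En * (1i * co$a * pt$tau * Dh - co$b * pt$pi * hn))
      Ef <- sum(En * (-1i * co$a * pt$pi * Dh + co$b * pt$tau * hn))
      Er <- Er * cp[ii]; Et <- Et * cp[ii]; Ef <- Ef * sp[ii]
      # incident plane wave E0 x_c exp(i k z_c)
      Einc <- c(E0 * exp(1i * k * pts[ii, 3]), 0, 0)  # cartesian canonical
      Ec_sph <- c(Er, Et, Ef)
      Ec <- Ec_sph
      # convert scattered spherical -> canonical cartesian, then add incident
      Ec <- .sph_to_cart(Ec_sph, ct[ii], st[ii], cp[ii], sp[ii]) + Einc
      out_c[ii, ] <- Ec
      next
    }
    out_c[ii, ] <- .sph_to_cart(Ec, ct[ii], st[ii], cp[ii], sp[ii])
  }
  out_c %*% R   # canonical -> lab (R orthogonal: inverse = transpose)
}

.sph_to_cart <- function(E, ct, st, cp, sp) {
  c(E[1] * st * cp + E[2] * ct * cp - E[3] * sp,
    E[1] * st * sp + E[2] * ct * sp + E[3] * cp,
    E[1] * ct - E[2] * st)
}
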
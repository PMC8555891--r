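# shared fixtures and independent oracles

# one-row tissue table for custom homogeneous spheres
tissue_row <- function(eps_r, sigma, rho = 1000, cp = 3600,
                       c_bulk = 1450, beta = 3.6e-4, name = "tissue") {
  tibble::tibble(name = name, label = 5L, eps_r = eps_r, sigma = sigma,
                 rho = rho, cp = cp, alpha = beta / 3, beta = beta,
                 c_bulk = c_bulk, K = rho * c_bulk^2)
}

# all-vacuum phantom for plane-wave propagation tests
vacuum_phantom <- function(n = 20L, spacing = 5e-3, frequency = 1e9) {
  structure(list(
    labels = array(0L, dim = c(n, n, n)), spacing = spacing,
    tissue_table = tissue_property_table(frequency, include_vacuum = TRUE),
    head_length = n * spacing,
    probes = tibble::tibble(name = "centre", i = n %/% 2L, j = n %/% 2L,
                            k = n %/% 2L),
    frequency = frequency), class = "hpm_phantom")
}

# brute-force 10-g-style averaging oracle: direct triple-loop cube growth,
# independent of the integral-image implementation under test
brute_force_peak_avg <- function(field, labels, rho_of_label, spacing,
                                 group_labels, grams = 10) {
  d <- dim(field)
  rho <- array(rho_of_label[labels + 1L], dim = d)
  mass <- rho * spacing^3
  target <- grams / 1000
  best <- -Inf
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (!(labels[i, j, k] %in% group_labels)) next
    for (h in 1:max(d)) {
      xr <- max(1, i - h):min(d[1], i + h)
      yr <- max(1, j - h):min(d[2], j + h)
      zr <- max(1, k - h):min(d[3], k + h)
      m <- sum(mass[xr, yr, zr])
      if (m >= target) {
        avg <- sum(field[xr, yr, zr] * mass[xr, yr, zr]) / m
        if (avg > best) best <- avg
        break
      }
    }
  }
  best
}

# local maxima of a spectrum above 1 kHz (for mode-set comparisons)
spectrum_peaks <- function(spec, fmax = 3e4) {
  f <- spec$frequency_Hz
  a <- spec$amplitude
  loc <- which(diff(sign(diff(a))) == -2) + 1
  f[loc[f[loc] > 1e3 & f[loc] < fmax]]
}

# cached small-scale pipeline runs (shared across test files; each
# configuration is computed once per session)
.run_cache <- new.env(parent = emptyenv())
small_head_args <- function() {
  list(outer_diameter = 0.096,
       layer_thicknesses = c(skin = 3e-3, skull = 5e-3, csf = 3e-3,
                             gray = 5e-3),
       spacing = 2e-3)
}
small_scenario <- function(pin = 1e6) {
  exposure_scenario(frequency = 1e9, pin = pin, tau_d = 5e-6,
                    direction = "+y", em_spacing = 2e-3,
                    wave_spacing = 2.5e-3, duration = 2e-3,
                    phantom_args = small_head_args())
}
small_run <- function(pin = 1e6) {
  key <- paste0("run_", format(pin, digits = 12))
  if (!exists(key, envir = .run_cache))
    assign(key, run_pipeline(small_scenario(pin)), envir = .run_cache)
  get(key, envir = .run_cache)
}
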
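#' @title Spectral analysis, extrema and injury assessment
#' @name injury
NULL

#' Amplitude spectrum of a pressure history
#'
#' One-sided FFT amplitude spectrum of a uniformly sampled probe trace
#' (rectangular window, 4x zero padding), with the dominant peak located
#' above `min_peak_freq` and refined by parabolic interpolation between
#' bins — the analysis used to read off the microwave-auditory (Frey
#' effect) tone of a pulse exposure.
#'
#' @param trace A two-column data frame (`time_s`, pressure) or a wide
#'   trace tibble from a wave solver; in the latter case `probe` selects
#'   the column (default: first probe).
#' @param probe Probe name when `trace` is a wide trace tibble.
#' @param pad Zero-padding factor (default 4).
#' @param min_peak_freq Lowest frequency considered for the dominant peak,
#'   Hz (default 1 kHz, below which the slow drift of the trace dominates).
#' @return An `hpm_spectrum` tibble (`frequency_Hz`, `amplitude`) with
#'   attributes `dominant_peak_Hz` and `probe`.
#' @export
pressure_spectrum <- function(trace, probe = NULL, pad = 4,
                              min_peak_freq = 1e3) {
  if (inherits(trace, "hpm_waveresult")) trace <- trace$traces
  tr <- tibble::as_tibble(trace)
  if (!"time_s" %in% names(tr))
    abort("Trace needs a `time_s` column.", class = "hpmwave_error_schema")
  pcols <- setdiff(names(tr), "time_s")
  col <- if (is.null(probe)) pcols[1] else {
    hit <- grep(paste0("^p_", probe, "_Pa$"), pcols, value = TRUE)
    if (length(hit) == 0 && probe %in% pcols) probe
    else if (length(hit) == 1) hit
    else abort("Probe not found in trace.", class = "hpmwave_error_domain")
  }
  t <- tr$time_s
  x <- tr[[col]]
  dts <- diff(t)
  if (length(dts) < 2 || max(abs(dts - dts[1])) > 1e-6 * dts[1])
    abort("Trace sampling is not uniform.", class = "hpmwave_error_sampling")
  dt <- dts[1]
  n <- length(x)
  nfft <- pad * 2^ceiling(log2(n))
  X <- fft(c(x - mean(x), numeric(nfft - n)))
  nh <- nfft %/% 2 + 1
  amp <- Mod(X[seq_len(nh)]) * 2 / n
  amp[1] <- amp[1] / 2
  freq <- (seq_len(nh) - 1) / (nfft * dt)

  cand <- which(freq >= min_peak_freq & seq_len(nh) > 1 & seq_len(nh) < nh)
  pk <- cand[which.max(amp[cand])]
  # parabolic interpolation on log-amplitude neighbours
  a0 <- amp[pk - 1]; a1 <- amp[pk]; a2 <- amp[pk + 1]
  denom <- a0 - 2 * a1 + a2
  delta <- if (abs(denom) > 0) 0.5 * (a0 - a2) / denom else 0
  delta <- max(min(delta, 0.5), -0.5)
  peak <- (pk - 1 + delta) / (nfft * dt)

  out <- tibble::tibble(frequency_Hz = freq, amplitude = amp)
  class(out) <- c("hpm_spectrum", class(out))
  attr(out, "dominant_peak_Hz") <- peak
  attr(out, "probe") <- sub("^p_(.*)_Pa$", "\\1", col)
  out
}

#' Dominant spectral peak
#'
#' @param spectrum An `hpm_spectrum`.
#' @return Peak frequency, Hz.
#' @export
dominant_peak <- function(spectrum) attr(spectrum, "dominant_peak_Hz")

#' @export
autoplot.hpm_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$frequency_Hz / 1e3,
                                       y = .data$amplitude)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(xlim = c(0, 30)) +
    ggplot2::labs(x = "frequency (kHz)", y = "amplitude (Pa per bin)")
}

#' Pressure/strain extrema of a wave-field history
#'
#' For a solver result, returns the stored per-voxel minimum-pressure map
#' and global strain extrema. For an explicit history (list with `times`
#' and `fields`, a list of co-registered pressure arrays), computes the
#' per-voxel minimum over time.
#'
#' @param history An `hpm_wave` result or `list(times=, fields=)`.
#' @return List: `min_pressure_map`, `min_pressure` (global, Pa), `mps`,
#'   `max_strain_rate` (NA when unavailable).
#' @export
extrema_maps <- function(history) {
  if (inherits(history, "hpm_wave")) {
    return(list(min_pressure_map = history$min_pressure,
                min_pressure = min(history$min_pressure),
                mps = history$mps,
                max_strain_rate = history$max_strain_rate))
  }
  if (is.list(history) && !is.null(history$fields)) {
    if (length(history$fields) == 0)
      abort("Empty field history.", class = "hpmwave_error_domain")
    mp <- Reduce(pmin, history$fields)
    return(list(min_pressure_map = mp, min_pressure = min(mp),
                mps = NA_real_, max_strain_rate = NA_real_))
  }
  abort("Unsupported history object.", class = "hpmwave_error_domain")
}

#' Injury-threshold assessment
#'
#' Compares tensile-pressure and strain extrema against the packaged
#' threshold table ([injury_thresholds()]): the cavitation flag trips at
#' the conservative -100 kPa edge of the -100 to -150 kPa band, the strain
#' flag at the classic 18% axonal threshold (with a separate high-rate
#' 3-6% band flag), and the minimum pressure magnitude is placed relative
#' to the 20-120 kPa band reported for NFL-style head impacts.
#'
#' @param extrema List as returned by [extrema_maps()] (fields
#'   `min_pressure`, `mps`, `max_strain_rate`).
#' @param thresholds Threshold table; defaults to [injury_thresholds()].
#' @return An `hpm_injury` list: stored extrema, `cavitation_flag`,
#'   `strain_flag`, `strain_flag_high_rate`, `nfl_band_comparison`
#'   (`"below"`, `"within"`, `"above"`).
#' @export
assess_injury <- function(extrema, thresholds = injury_thresholds()) {
  th <- function(metric) thresholds[thresholds$metric == metric, ]
  minp <- extrema$min_pressure
  mps <- extrema$mps
  cav <- th("cavitation_pressure")
  nfl <- th("nfl_impact_pressure")
  out <- list(
    max_tensile_pressure_Pa = minp,
    mps = mps,
    max_strain_rate = extrema$max_strain_rate,
    cavitation_flag = is.finite(minp) && minp <= cav$upper,
    strain_flag = is.finite(mps) && mps >= th("axonal_strain")$lower,
    strain_flag_high_rate = is.finite(mps) &&
      mps >= th("axonal_strain_high_rate")$lower,
    nfl_band_comparison = if (!is.finite(minp)) NA_character_
      else if (abs(minp) < nfl$lower) "below"
      else if (abs(minp) <= nfl$upper) "within"
      else "above"
  )
  structure(out, class = "hpm_injury")
}

#' @export
print.hpm_injury <- function(x, ...) {
  cat(sprintf("<hpm_injury> min pressure %.4g kPa | MPS %.3g | rate %.3g /s\n",
              x$max_tensile_pressure_Pa / 1e3, x$mps, x$max_strain_rate))
  cat(sprintf("  cavitation: %s | strain (18%%): %s | high-rate band: %s | NFL band: %s\n",
              x$cavitation_flag, x$strain_flag, x$strain_flag_high_rate,
              x$nfl_band_comparison))
  invisible(x)
}

#' @export
tidy.hpm_injury <- function(x, ...) {
  tibble::tibble(
    metric = c("max_tensile_pressure_Pa", "mps", "max_strain_rate"),
    value = c(x$max_tensile_pressure_Pa, x$mps, x$max_strain_rate),
    flagged = c(x$cavitation_flag, x$strain_flag, x$strain_flag_high_rate)
  )
}

#' Power-density sweep by linearity
#'
#' The whole chain from incident power density to pressure is linear:
#' temperature rise is `PIN * SAR* * tau_d / cp` and the wave equations
#' are linear in the forcing. A sweep therefore needs one reference run,
#' whose peak tensile pressure and peak temperature are scaled to each
#' requested power density. With `verify = TRUE` the wave stage is re-run
#' at the largest requested density and compared against the scaled
#' prediction; deviation beyond 1% flags (unexpected) nonlinearity.
#'
#' @param run An `hpm_run` from [run_pipeline()] (the reference).
#' @param pins Power densities to tabulate, mW/cm^2.
#' @param verify Re-run the wave stage at `max(pins)` as a check.
#' @return An `hpm_sweep` tibble: `pin_mW_cm2`, `max_tensile_pressure_Pa`,
#'   `peak_dT_C`; attribute `nonlinearity` (relative deviation, or NA).
#' @export
power_sweep <- function(run, pins, verify = FALSE) {
  stopifnot(inherits(run, "hpm_run"))
  ref_pin <- run$scenario$pin
  ref_p <- min(run$wave$min_pressure)
  ref_dT <- max(run$load$delta_T)
  out <- tibble::tibble(
    pin_mW_cm2 = pins,
    max_tensile_pressure_Pa = abs(ref_p) * pins / ref_pin,
    peak_dT_C = ref_dT * pins / ref_pin
  )
  nonlin <- NA_real_
  if (verify) {
    k <- max(pins) / ref_pin
    load2 <- run$wave_load
    load2$delta_T <- load2$delta_T * k
    load2$pin <- max(pins)
    w2 <- solve_cartesian(run$wave_phantom, load2, run$wave$duration,
                          skull = run$wave$skull, track_strain = FALSE)
    pred <- abs(ref_p) * k
    nonlin <- abs(abs(min(w2$min_pressure)) - pred) / pred
    if (nonlin > 0.01)
      warn(sprintf("Sweep linearity check deviates by %.2g%%.",
                   100 * nonlin))
  }
  class(out) <- c("hpm_sweep", class(out))
  attr(out, "nonlinearity") <- nonlin
  out
}

#' @export
autoplot.hpm_sweep <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$pin_mW_cm2,
                               y = .data$max_tensile_pressure_Pa / 1e3)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "incident power density (mW/cm^2)",
                  y = "max tensile pressure (kPa)")
}

#' Far-field power density of a directive antenna
#'
#' `S = P G / (4 pi R^2)` with gain in dBi, converted to mW/cm^2 — the
#' link-budget arithmetic used to place high-power microwave scenarios at
#' range (e.g. ~8 MW through a 40-dBi antenna gives ~1e6 mW/cm^2 at 25 m).
#'
#' @param source_power Transmitted peak power, W.
#' @param gain_dBi Antenna gain, dBi.
#' @param range Distance, m (> 0).
#' @return Power density, mW/cm^2.
#' @export
power_density_at_range <- function(source_power, gain_dBi, range) {
  if (range <= 0) abort("`range` must be positive.",
                        class = "hpmwave_error_domain")
  source_power * 10^(gain_dBi / 10) / (4 * pi * range^2) / .const$mwcm2
}

#' Energy density of a single pulse
#'
#' `PIN * tau_d` in J/m^2 (power density supplied in W/m^2).
#'
#' @param pin Incident power density, W/m^2.
#' @param tau_d Pulse duration, s.
#' @return Energy density, J/m^2.
#' @export
pulse_energy_density <- function(pin, tau_d) {
  if (pin < 0 || tau_d < 0)
    abort("Inputs must be non-negative.", class = "hpmwave_error_domain")
  pin * tau_d
}

#' IEEE C95.1 exposure reference limit and averaged energy density
#'
#' In the 400 MHz - 2 GHz band the whole-body exposure reference limit is
#' `f_MHz / 200` W/m^2, time-averaged over 30 minutes; the corresponding
#' energy density over `averaging_time` is their product.
#'
#' @param frequency Carrier frequency, Hz (400 MHz - 2 GHz).
#' @param averaging_time Averaging time, s (default 30 min).
#' @return List with `erl_W_m2` and `energy_J_m2`.
#' @export
erl_energy <- function(frequency, averaging_time = 1800) {
  f_mhz <- frequency / 1e6
  if (f_mhz < 400 || f_mhz > 2000)
    abort("ERL formula f_MHz/200 applies to 400 MHz - 2 GHz only.",
          class = "hpmwave_error_range")
  erl <- f_mhz / 200
  list(erl_W_m2 = erl, energy_J_m2 = erl * averaging_time)
}
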
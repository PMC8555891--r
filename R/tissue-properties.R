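#' Tissue labels used by the layered head phantom
#'
#' Integer voxel labels: 0 is free space (outside the body) and never appears
#' in the tissue table; ventricles carry CSF material properties under their
#' own label so they can be addressed separately.
#'
#' @format Named integer vector.
#' @export
tissue_labels <- c(
  vacuum = 0L, skin = 1L, skull = 2L, csf = 3L,
  gray = 4L, white = 5L, ventricle = 6L
)

# Dielectric anchors (relative permittivity, conductivity S/m) at
# 0.4, 1, 2 and 3 GHz, Gabriel/IT'IS-typical values for adult tissue.
# Single-frequency lookup with linear interpolation between anchors; no
# dispersive (Debye/Cole-Cole) model is fitted.
.diel_anchor_ghz <- c(0.4, 1, 2, 3)
.diel_anchors <- list(
  skin  = list(eps_r = c(46.1, 40.9, 38.6, 37.4), sigma = c(0.70, 0.90, 1.27, 1.74)),
  skull = list(eps_r = c(13.1, 12.4, 11.7, 11.1), sigma = c(0.09, 0.156, 0.31, 0.51)),
  csf   = list(eps_r = c(70.6, 68.4, 66.9, 66.2), sigma = c(2.25, 2.46, 3.00, 3.66)),
  gray  = list(eps_r = c(57.4, 52.3, 49.7, 48.0), sigma = c(0.79, 0.985, 1.43, 2.05)),
  white = list(eps_r = c(42.0, 38.6, 36.8, 35.5), sigma = c(0.45, 0.622, 0.95, 1.41))
)

# Frequency-independent thermo-acoustic constants.
#   rho kg/m^3, cp J/(kg K), alpha 1/degC (linear expansion; beta = 3*alpha),
#   c_bulk m/s.  Brain bulk wave speed 1450 m/s and bone alpha 0.27e-4/degC
#   anchor the table; brain/CSF expansion is water-like at body temperature
#   (beta ~ 3.6e-4/degC). Bone expansion is mechanically inert in the wave
#   solvers but the tabulated alpha is kept for reporting.
.thermo_acoustic <- tibble::tribble(
  ~name,      ~rho, ~cp,  ~alpha,    ~c_bulk,
  "skin",     1109, 3400, 1.2e-4,    1540,
  "skull",    1908, 1300, 0.27e-4,   2900,
  "csf",      1007, 4100, 1.2e-4,    1500,
  "gray",     1040, 3600, 1.2e-4,    1450,
  "white",    1040, 3600, 1.2e-4,    1450,
  "ventricle",1007, 4100, 1.2e-4,    1500
)

#' Per-tissue physical property table at a carrier frequency
#'
#' Returns one row per tissue label with the dielectric properties
#' interpolated to `frequency` and frequency-independent thermal/acoustic
#' constants. Dielectrics are Gabriel-style literature-typical values
#' anchored at 0.4, 1, 2 and 3 GHz; the brain bulk wave speed is 1450 m/s
#' and cortical-bone linear thermal expansion 0.27e-4 per degree C. The
#' bulk modulus is derived as `K = rho * c_bulk^2`, so the two are
#' consistent by construction.
#'
#' @param frequency Carrier frequency in Hz; must lie in 0.4-3 GHz.
#' @param include_vacuum Add a `vacuum` row (label 0) with `eps_r = 1`,
#'   `sigma = 0` and zero density/heat capacity. Useful for solvers that
#'   index properties by label; excluded from physical-positivity checks.
#'
#' @return A tibble with columns `name`, `label`, `eps_r`, `sigma`, `rho`,
#'   `cp`, `alpha`, `beta`, `c_bulk`, `K`.
#' @export
#' @examples
#' tissue_property_table(1e9)
tissue_property_table <- function(frequency, include_vacuum = FALSE) {
  if (!is.numeric(frequency) || length(frequency) != 1 || !is.finite(frequency))
    abort("`frequency` must be a single finite number (Hz).",
          class = "hpmwave_error_domain")
  f_ghz <- frequency / 1e9
  if (f_ghz < 0.4 || f_ghz > 3)
    abort(sprintf(
      "Frequency %.3g GHz outside the supported 0.4-3 GHz dielectric band.",
      f_ghz), class = "hpmwave_error_range")

  diel <- dplyr::bind_rows(lapply(names(.diel_anchors), function(nm) {
    a <- .diel_anchors[[nm]]
    tibble::tibble(
      name  = nm,
      eps_r = stats::approx(.diel_anchor_ghz, a$eps_r, xout = f_ghz)$y,
      sigma = stats::approx(.diel_anchor_ghz, a$sigma, xout = f_ghz)$y
    )
  }))
  # ventricles are CSF-filled
  diel <- dplyr::bind_rows(
    diel,
    dplyr::mutate(dplyr::filter(diel, .data$name == "csf"), name = "ventricle")
  )

  tab <- dplyr::inner_join(diel, .thermo_acoustic, by = "name")
  tab <- dplyr::mutate(tab,
    label  = unname(tissue_labels[.data$name]),
    beta   = 3 * .data$alpha,
    K      = .data$rho * .data$c_bulk^2
  )
  if (include_vacuum) {
    tab <- dplyr::bind_rows(tab, tibble::tibble(
      name = "vacuum", eps_r = 1, sigma = 0, rho = 0, cp = 0,
      alpha = 0, c_bulk = 0, label = 0L, beta = 0, K = 0
    ))
  }
  tab <- dplyr::arrange(tab, .data$label)
  dplyr::select(tab, "name", "label", "eps_r", "sigma", "rho", "cp",
                "alpha", "beta", "c_bulk", "K")
  }

#' Validate a tissue property table
#'
#' Checks the physical invariants: strictly positive constants (conductivity
#' may be zero) and mutual consistency of bulk modulus and wave speed
#' (`K = rho * c_bulk^2` to 1e-9 relative). The vacuum row (label 0) is
#' exempt from positivity.
#'
#' @param table A tibble as returned by [tissue_property_table()].
#' @return Invisibly `table`; aborts on violation.
#' @export
validate_tissue_table <- function(table) {
  need <- c("name", "label", "eps_r", "sigma", "rho", "cp", "alpha",
            "beta", "c_bulk", "K")
  if (!all(need %in% names(table)))
    abort("Tissue table missing required columns.",
          class = "hpmwave_error_schema")
  phys <- table[table$label != 0L, ]
  pos_cols <- c("eps_r", "rho", "cp", "c_bulk", "K")
  for (cl in pos_cols)
    if (any(phys[[cl]] <= 0))
      abort(sprintf("Tissue column `%s` must be strictly positive.", cl),
            class = "hpmwave_error_domain")
  if (any(table$sigma < 0) || any(phys$alpha < 0))
    abort("`sigma` and `alpha` must be non-negative.",
          class = "hpmwave_error_domain")
  rel <- abs(phys$K - phys$rho * phys$c_bulk^2) / phys$K
  if (any(rel > 1e-9))
    abort("Bulk modulus inconsistent with rho * c_bulk^2.",
          class = "hpmwave_error_domain")
  invisible(table)
}

#' Mechanics-based brain injury thresholds
#'
#' One central constants table used by [assess_injury()]: the commonly cited
#' brain cavitation band (tensile pressures of -100 to -150 kPa), the classic
#' 18% axonal strain threshold with its 3-6% high-rate variant, and the
#' 20-120 kPa tensile-pressure band reported for NFL-style head impacts.
#'
#' @return A tibble with columns `metric`, `lower`, `upper`, `units`.
#' @export
injury_thresholds <- function() {
  tibble::tribble(
    ~metric,                 ~lower,   ~upper,   ~units,
    "cavitation_pressure",   -150e3,   -100e3,   "Pa",
    "axonal_strain",          0.18,     0.18,    "1",
    "axonal_strain_high_rate",0.03,     0.06,    "1",
    "nfl_impact_pressure",    20e3,     120e3,   "Pa"
  )
}
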
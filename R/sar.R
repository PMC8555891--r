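#' @title SAR computation, normalization and 10-g averaging
#' @name sar
NULL

new_sar_map <- function(sar, sar_star = NULL, pin_ref = NA_real_,
                        peak10g = NULL) {
  structure(list(sar = sar, sar_star = sar_star, pin_ref = pin_ref,
                 peak10g = peak10g), class = "hpm_sar")
}

#' @export
print.hpm_sar <- function(x, ...) {
  cat(sprintf("<hpm_sar> peak voxel SAR %.4g W/kg", max(x$sar)))
  if (!is.null(x$sar_star))
    cat(sprintf("; SAR* normalized at %.4g mW/cm^2", x$pin_ref))
  cat("\n")
  if (!is.null(x$peak10g)) print(x$peak10g)
  invisible(x)
}

#' Specific absorption rate from an RMS field
#'
#' `SAR = sigma |E|^2 / rho` per voxel, with `E` the RMS electric field.
#' Voxels with zero conductivity (including all free space) are exactly 0.
#'
#' @param field An `hpm_field` from [run_fdtd()], or an RMS E-magnitude
#'   array co-registered with the phantom (V/m).
#' @param phantom The `hpm_phantom` the field was computed on.
#' @return An `hpm_sar` with the `sar` array filled (W/kg).
#' @export
compute_sar <- function(field, phantom) {
  rms <- if (inherits(field, "hpm_field")) field$rms_E else field
  if (!identical(dim(rms), dim(phantom$labels)))
    abort("RMS field is not co-registered with the phantom.",
          class = "hpmwave_error_registration")
  sig <- .voxel_property(phantom, "sigma", fill = 0)
  rho <- .voxel_property(phantom, "rho", fill = 0)
  sar <- array(0, dim = dim(rms))
  ok <- sig > 0 & rho > 0
  sar[ok] <- sig[ok] * rms[ok]^2 / rho[ok]
  new_sar_map(sar)
}

#' Normalize SAR by incident power density
#'
#' Fills the `sar_star` slot: `SAR* = SAR / PIN` with units
#' (W/kg)/(mW/cm^2). SAR* is independent of the source amplitude used in
#' the FDTD run, so it can later be scaled to any exposure.
#'
#' @param sar_map An `hpm_sar`.
#' @param pin Incident power density of the source used, mW/cm^2 (for a
#'   free-space amplitude `E0` this is [incident_power_density()]).
#' @return The `hpm_sar` with `sar_star` and `pin_ref` filled.
#' @export
normalize_sar <- function(sar_map, pin) {
  stopifnot(inherits(sar_map, "hpm_sar"))
  if (!is.numeric(pin) || length(pin) != 1 || pin <= 0)
    abort("`pin` must be a positive power density (mW/cm^2).",
          class = "hpmwave_error_domain")
  sar_map$sar_star <- sar_map$sar / pin
  sar_map$pin_ref <- pin
  sar_map
}

# padded 3D integral image: P[i+1,j+1,k+1] = sum A[1:i,1:j,1:k]
.integral3 <- function(a) {
  d <- dim(a)
  p <- array(0, dim = d + 1L)
  p[-1, -1, -1] <- a
  p <- aperm(apply(p, c(2, 3), cumsum), c(1, 2, 3))
  p <- aperm(apply(p, c(1, 3), cumsum), c(2, 1, 3))
  aperm(apply(p, c(1, 2), cumsum), c(2, 3, 1))
}

# clipped-cube sums at voxel rows `ix` (matrix i,j,k), half-width h
.cube_sum <- function(P, ix, h, d) {
  lo <- pmax(ix - h, 1L); hi <- pmin(ix + h, matrix(d, nrow(ix), 3, byrow = TRUE))
  g <- function(a, b, c) P[cbind(a, b, c)]
  x0 <- lo[, 1]; y0 <- lo[, 2]; z0 <- lo[, 3]
  x1 <- hi[, 1] + 1L; y1 <- hi[, 2] + 1L; z1 <- hi[, 3] + 1L
  g(x1, y1, z1) - g(x0, y1, z1) - g(x1, y0, z1) - g(x1, y1, z0) +
    g(x0, y0, z1) + g(x0, y1, z0) + g(x1, y0, z0) - g(x0, y0, z0)
}

#' Peak 10-g averaged SAR* over a tissue group
#'
#' IEEE C95.1-style localized-exposure metric: for every voxel of the
#' group, a centred cube is grown voxel-by-voxel until the tissue mass it
#' encloses (density times voxel volume, air excluded) reaches `grams`;
#' the mass-averaged SAR* over the cube's in-body voxels is recorded and
#' the maximum over the group returned. Cubes are clipped at the grid
#' boundary; clipped voxels contribute no mass.
#'
#' @param sar_map An `hpm_sar` (uses `sar_star` if present, else `sar`).
#' @param phantom The phantom.
#' @param group Character tissue names or integer labels defining the
#'   group (e.g. `c("gray", "white", "csf", "ventricle")`).
#' @param grams Averaging mass, g (default 10).
#' @return Peak averaged value (same units as the input field), with the
#'   peak voxel index as attribute `voxel`.
#' @export
average_sar_10g <- function(sar_map, phantom, group, grams = 10) {
  stopifnot(inherits(sar_map, "hpm_sar"))
  fld <- sar_map$sar_star %||% sar_map$sar
  labs <- if (is.character(group)) unname(tissue_labels[group]) else as.integer(group)
  if (any(is.na(labs)))
    abort("Unknown tissue group.", class = "hpmwave_error_domain")
  d <- dim(phantom$labels)
  rho <- .voxel_property(phantom, "rho", fill = 0)
  mass <- rho * phantom$spacing^3            # kg per voxel, 0 in air
  target <- grams / 1000
  sel <- which(array(phantom$labels %in% labs, dim = d))
  if (length(sel) == 0)
    abort("Tissue group empty in phantom.", class = "hpmwave_error_domain")
  if (sum(mass[sel]) < target)
    abort(sprintf("Group mass %.3g g below the %.3g g averaging mass.",
                  1000 * sum(mass[sel]), grams),
          class = "hpmwave_error_insufficient_mass")

  PM <- .integral3(mass)
  PS <- .integral3(fld * mass)
  ix <- arrayInd(sel, d)
  avg <- rep(NA_real_, length(sel))
  todo <- seq_along(sel)
  h <- 0L
  while (length(todo) > 0 && h <= max(d)) {
    h <- h + 1L
    msum <- .cube_sum(PM, ix[todo, , drop = FALSE], h, d)
    done <- msum >= target
    if (any(done)) {
      rows <- todo[done]
      ssum <- .cube_sum(PS, ix[rows, , drop = FALSE], h, d)
      avg[rows] <- ssum / msum[done]
      todo <- todo[!done]
    }
  }
  if (length(todo) > 0)
    abort("Averaging cube exhausted the grid before reaching target mass.",
          class = "hpmwave_error_insufficient_mass")
  best <- which.max(avg)
  structure(max(avg), voxel = ix[best, ])
}

#' Summarise peak 10-g SAR* for the conventional tissue groups
#'
#' @param sar_map An `hpm_sar`.
#' @param phantom The phantom.
#' @param grams Averaging mass in grams.
#' @return The `hpm_sar` with a `peak10g` tibble (`group`, `peak10g`).
#' @export
summarize_sar <- function(sar_map, phantom, grams = 10) {
  groups <- list(
    intracranial = c("csf", "gray", "white", "ventricle"),
    skin = "skin"
  )
  present <- unique(as.integer(phantom$labels))
  rows <- lapply(names(groups), function(g) {
    labs <- unname(tissue_labels[groups[[g]]])
    labs <- labs[labs %in% present]
    if (length(labs) == 0) return(NULL)
    tibble::tibble(group = g,
                   peak10g = as.numeric(average_sar_10g(sar_map, phantom,
                                                        labs, grams)))
  })
  sar_map$peak10g <- dplyr::bind_rows(rows)
  sar_map
}

#' Tidy per-tissue SAR summary
#'
#' @param x An `hpm_sar`.
#' @param phantom The phantom the map was computed on.
#' @param ... Unused.
#' @return Tibble with per-tissue mean and max SAR (and SAR* if present).
#' @export
tidy.hpm_sar <- function(x, phantom, ...) {
  tab <- phantom$tissue_table
  rows <- lapply(seq_len(nrow(tab)), function(r) {
    m <- phantom$labels == tab$label[r]
    if (!any(m)) return(NULL)
    out <- tibble::tibble(
      tissue = tab$name[r],
      mean_sar = mean(x$sar[m]),
      max_sar = max(x$sar[m])
    )
    if (!is.null(x$sar_star)) {
      out$mean_sar_star <- mean(x$sar_star[m])
      out$max_sar_star <- max(x$sar_star[m])
    }
    out
  })
  dplyr::bind_rows(rows)
}
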
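#' @title Voxel head phantoms
#' @description Synthetic layered-ellipsoid stand-ins for a segmented
#'   MRI-derived head model: concentric shells labelled outside-in
#'   skin, skull, CSF, gray matter, white matter, with an optional
#'   CSF-filled ventricle inclusion at the centre.
#' @name phantom
NULL

.brain_labels <- c(3L, 4L, 5L, 6L)   # csf counted as intracranial contents
.intracranial_labels <- c(3L, 4L, 5L, 6L)

new_phantom <- function(labels, spacing, tissue_table, head_length, probes,
                        frequency) {
  structure(
    list(labels = labels, spacing = spacing, tissue_table = tissue_table,
         head_length = head_length, probes = probes, frequency = frequency),
    class = "hpm_phantom")
}

#' @export
print.hpm_phantom <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<hpm_phantom> %d x %d x %d voxels @ %.3g mm\n",
              d[1], d[2], d[3], x$spacing * 1e3))
  cat(sprintf("  head length (AP, cranium): %.3f m\n", x$head_length))
  tab <- table(x$labels[x$labels > 0])
  nm <- names(tissue_labels)[match(as.integer(names(tab)), tissue_labels)]
  cat("  voxels:", paste(sprintf("%s=%d", nm, tab), collapse = ", "), "\n")
  cat("  probes:", paste(x$probes$name, collapse = ", "), "\n")
  invisible(x)
}

# voxel-centre coordinate vectors (m), origin at grid corner
.axis_coords <- function(n, spacing) (seq_len(n) - 0.5) * spacing

# `centre` is in voxel units (e.g. dims/2): offsets are computed in voxel
# units first so mirror-symmetric pairs are exact in floating point and
# boundary ties classify symmetrically
.ellipsoid_mask <- function(dims, spacing, centre, semi) {
  ax <- function(n, c0) (seq_len(n) - 0.5 - c0) * spacing
  xs <- ax(dims[1], centre[1])
  ys <- ax(dims[2], centre[2])
  zs <- ax(dims[3], centre[3])
  q <- outer(outer((xs / semi[1])^2, (ys / semi[2])^2, `+`),
             (zs / semi[3])^2, `+`)
  q <= 1
}

#' Build a layered ellipsoidal head phantom
#'
#' Concentric shells are generated outside-in as skin, skull, CSF and gray
#' matter, with the remaining interior labelled white matter. `outer_diameter`
#' is the anterior-posterior (AP, y-axis) extent of the *skin* surface; the
#' phantom's `head_length` is the AP extent of the cranium (skull outer
#' surface), i.e. `outer_diameter - 2 * skin thickness`. With the defaults
#' (skin 3 mm, skull 7 mm, CSF 3 mm, skin-to-skin 0.176 m) the cranium spans
#' 0.17 m and the brain compartment 0.15 m along AP.
#'
#' Axis convention: x = left-right, y = posterior-anterior, z =
#' inferior-superior; a "frontal" exposure propagates along +y, a "side"
#' exposure along +x. Voxel indices are 1-based as usual in R.
#'
#' @param outer_diameter AP extent of the outermost (skin) surface, m.
#' @param layer_thicknesses Named numeric vector of shell thicknesses (m);
#'   recognised names, outside-in: `skin`, `skull`, `csf`, `gray`. Layers may
#'   be omitted (e.g. no skin); the interior is always white matter.
#' @param spacing Voxel edge length, m.
#' @param shape `"ellipsoid"` (default) or `"sphere"`. The ellipsoid scales
#'   the left-right and inferior-superior semi-axes by `aspect`.
#' @param aspect Length-2 numeric, LR and IS semi-axes relative to AP
#'   (ignored for spheres).
#' @param include_ventricles Carve a small CSF-filled ellipsoid (label
#'   `ventricle`) at the brain centre.
#' @param frequency Carrier frequency (Hz) at which the attached tissue
#'   property table is evaluated.
#' @param margin Vacuum margin around the phantom, in voxels.
#'
#' @return An `hpm_phantom`: voxel label volume, spacing, tissue table,
#'   `head_length`, and a probe tibble (frontal at 25% of the brain AP axis,
#'   periventricular at the centre, occipital at 75%).
#' @export
#' @examples
#' ph <- build_layered_head(spacing = 4e-3)
#' ph
build_layered_head <- function(outer_diameter = 0.176,
                               layer_thicknesses = c(skin = 3e-3, skull = 7e-3,
                                                     csf = 3e-3, gray = 6e-3),
                               spacing = 2e-3,
                               shape = c("ellipsoid", "sphere"),
                               aspect = c(0.85, 1.0),
                               include_ventricles = TRUE,
                               frequency = 1e9,
                               margin = 1L) {
  shape <- match.arg(shape)
  if (!is.numeric(spacing) || spacing <= 0)
    abort("`spacing` must be positive.", class = "hpmwave_error_domain")
  lt <- layer_thicknesses
  allowed <- c("skin", "skull", "csf", "gray")
  if (length(lt) && (is.null(names(lt)) || !all(names(lt) %in% allowed)))
    abort("`layer_thicknesses` must be named among skin/skull/csf/gray.",
          class = "hpmwave_error_domain")
  a_ap <- outer_diameter / 2
  if (sum(lt) >= a_ap)
    abort("Layer thicknesses meet or exceed the outer radius.",
          class = "hpmwave_error_geometry")
  if (length(lt) && spacing > min(lt))
    abort(sprintf(
      "Voxel spacing %.3g m cannot resolve the thinnest layer (%.3g m).",
      spacing, min(lt)), class = "hpmwave_error_resolution")

  if (shape == "sphere") aspect <- c(1, 1)
  semi0 <- c(a_ap * aspect[1], a_ap, a_ap * aspect[2])
  dims <- ceiling(2 * semi0 / spacing) + 2L * margin
  dims <- as.integer(dims + (dims %% 2L == 0L))  # odd dims: centre on a voxel
  centre <- dims / 2

  labels <- array(0L, dim = dims)
  # outside-in: each shell is the set difference of successive ellipsoids
  order_names <- intersect(allowed, names(lt))
  semi <- semi0
  prev <- .ellipsoid_mask(dims, spacing, centre, semi)
  shell_label <- function(nm) unname(tissue_labels[nm])
  for (nm in order_names) {
    semi <- semi - lt[[nm]]
    if (any(semi <= 0))
      abort("Layer thicknesses meet or exceed the outer radius.",
            class = "hpmwave_error_geometry")
    inner <- .ellipsoid_mask(dims, spacing, centre, semi)
    labels[prev & !inner] <- shell_label(nm)
    prev <- inner
  }
  labels[prev] <- tissue_labels[["white"]]
  if (include_ventricles) {
    vent <- .ellipsoid_mask(dims, spacing, centre,
                            semi = c(8e-3, 18e-3, 10e-3))
    labels[vent & prev] <- tissue_labels[["ventricle"]]
  }

  skin_t <- if ("skin" %in% names(lt)) lt[["skin"]] else 0
  head_length <- outer_diameter - 2 * skin_t
  tissue_table <- tissue_property_table(frequency)
  probes <- .default_probes(labels, spacing)
  ph <- new_phantom(labels, spacing, tissue_table, head_length, probes,
                    frequency)
  validate_phantom(ph)
}

#' Build a homogeneous sphere phantom
#'
#' A single-tissue sphere in vacuum, mainly for solver validation against
#' analytic (Mie, radial-eigenmode) references.
#'
#' @param radius Sphere radius, m.
#' @param spacing Voxel edge length, m.
#' @param properties One-row tissue table (see [tissue_property_table()]) or
#'   a tissue name from that table; defaults to white matter at `frequency`.
#' @param frequency Frequency for the default property lookup, Hz.
#' @param margin Vacuum margin in voxels.
#' @return An `hpm_phantom` with probes at centre and half-radius.
#' @export
build_sphere_phantom <- function(radius, spacing, properties = "white",
                                 frequency = 1e9, margin = 1L) {
  if (radius <= 0 || spacing <= 0)
    abort("`radius` and `spacing` must be positive.",
          class = "hpmwave_error_domain")
  if (is.character(properties)) {
    tab <- tissue_property_table(frequency)
    properties <- tab[tab$name == properties, ]
    if (nrow(properties) != 1)
      abort("Unknown tissue name.", class = "hpmwave_error_domain")
  }
  properties$label <- 5L
  properties$name <- properties$name %||% "tissue"
  n <- as.integer(ceiling(2 * radius / spacing) + 2L * margin)
  n <- n + (n %% 2L == 0L)
  dims <- c(n, n, n)
  centre <- dims / 2
  labels <- array(0L, dim = dims)
  labels[.ellipsoid_mask(dims, spacing, centre, rep(radius, 3))] <- 5L
  probes <- .default_probes(labels, spacing)
  new_phantom(labels, spacing, tibble::as_tibble(properties),
              head_length = 2 * radius, probes = probes, frequency = frequency)
}

# probes: frontal 25%, periventricular 50%, occipital 75% of the brain's
# AP (y) extent, on the x/z centreline, snapped to the nearest brain voxel.
.default_probes <- function(labels, spacing) {
  brain <- which(array(labels %in% .brain_labels | labels == 5L,
                       dim = dim(labels)), arr.ind = TRUE)
  if (nrow(brain) == 0)
    abort("Phantom contains no brain-labelled voxels.",
          class = "hpmwave_error_geometry")
  yr <- range(brain[, 2])
  xc <- round(mean(range(brain[, 1])))
  zc <- round(mean(range(brain[, 3])))
  frac <- c(frontal = 0.75, periventricular = 0.5, occipital = 0.25)
  # y increases anterior; frontal lies toward high y
  rows <- lapply(names(frac), function(nm) {
    yj <- round(yr[1] + frac[[nm]] * diff(yr))
    cand <- brain[brain[, 2] == yj, , drop = FALSE]
    if (nrow(cand) == 0) cand <- brain
    d2 <- (cand[, 1] - xc)^2 + (cand[, 3] - zc)^2
    v <- cand[which.min(d2), ]
    tibble::tibble(name = nm, i = v[1], j = v[2], k = v[3])
  })
  dplyr::bind_rows(rows)
}

#' Validate phantom invariants
#'
#' Every non-zero label must appear in the tissue table, the stored
#' `head_length` must match the labelled cranium extent to within one voxel,
#' and every probe must sit on a brain-labelled voxel.
#'
#' @param phantom An `hpm_phantom`.
#' @return Invisibly the phantom; aborts on violation.
#' @export
validate_phantom <- function(phantom) {
  stopifnot(inherits(phantom, "hpm_phantom"))
  labs <- sort(unique(as.integer(phantom$labels)))
  labs <- labs[labs != 0L]
  if (!all(labs %in% phantom$tissue_table$label))
    abort("Phantom labels missing from tissue table.",
          class = "hpmwave_error_schema")
  # cranium AP extent: labels excluding skin (and vacuum)
  core <- phantom$labels != 0L & phantom$labels != tissue_labels[["skin"]]
  if (any(core)) {
    jr <- range(which(apply(core, 2, any)))
    extent <- (diff(jr) + 1) * phantom$spacing
    if (abs(extent - phantom$head_length) > phantom$spacing + 1e-12)
      abort(sprintf(
        "head_length %.4f m inconsistent with labelled extent %.4f m.",
        phantom$head_length, extent), class = "hpmwave_error_geometry")
  }
  ok <- vapply(seq_len(nrow(phantom$probes)), function(r) {
    p <- phantom$probes[r, ]
    phantom$labels[p$i, p$j, p$k] %in% c(.brain_labels, 5L)
  }, logical(1))
  if (!all(ok))
    abort("Probe outside brain-labelled voxels.",
          class = "hpmwave_error_geometry")
  invisible(phantom)
}

# per-voxel lookup of a tissue-table column, vacuum -> `fill`
.voxel_property <- function(phantom, column, fill = 0) {
  tab <- phantom$tissue_table
  lut <- rep(fill, max(tab$label) + 1L)
  lut[tab$label + 1L] <- tab[[column]]
  array(lut[phantom$labels + 1L], dim = dim(phantom$labels))
}

#' Write / read a phantom as NIfTI plus JSON sidecar
#'
#' The label volume goes to a NIfTI file (voxel dimensions in mm, as is
#' conventional for NIfTI) and everything else (spacing, head length, tissue
#' table, probes, frequency) to `<path>.json`.
#'
#' @param phantom An `hpm_phantom`.
#' @param path Output NIfTI path (`.nii` or `.nii.gz`).
#' @return `write_phantom`: invisibly `path`; `read_phantom`: the phantom.
#' @export
write_phantom <- function(phantom, path) {
  img <- RNifti::asNifti(phantom$labels + 0)
  RNifti::pixdim(img) <- rep(phantom$spacing * 1e3, 3)
  RNifti::writeNifti(img, path)
  side <- list(
    spacing = phantom$spacing, head_length = phantom$head_length,
    frequency = phantom$frequency,
    tissue_table = phantom$tissue_table, probes = phantom$probes
  )
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) {
  img <- RNifti::readNifti(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  labels <- array(as.integer(round(as.array(img))), dim = dim(img))
  new_phantom(labels, side$spacing,
              tibble::as_tibble(side$tissue_table),
              side$head_length, tibble::as_tibble(side$probes),
              side$frequency)
}
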
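#' Reference cohort parameters for the six brain ROIs
#'
#' Group-level means and standard deviations of total sodium concentration
#' (TSC, mmol/L wet tissue) and of ICV-normalized volumes (% of intracranial
#' volume) for the six regions of interest analysed in the study cohort:
#' substantia nigra, putamen, caudate nucleus, pallidum, thalamus and cortical
#' gray matter, in early idiopathic Parkinson's disease patients (`iPD`) and
#' healthy controls (`HC`). These are the default ground-truth parameters of
#' the cohort simulator.
#'
#' @return A tibble with columns `roi`, `group`, `tsc_mean`, `tsc_sd`,
#'   `nvol_mean`, `nvol_sd`.
#' @export
roi_reference_values <- function() {
  tibble(
    roi = rep(brain_rois(), each = 2),
    group = rep(c("iPD", "HC"), times = 6),
    tsc_mean = c(43.73, 37.72, 48.65, 43.66, 54.22, 52.35,
                 45.80, 41.07, 50.60, 46.29, 56.34, 50.81),
    tsc_sd   = c(4.64, 5.62, 4.58, 5.04, 4.36, 5.50,
                 4.19, 4.94, 5.92, 5.14, 3.92, 5.50),
    nvol_mean = c(0.07, 0.08, 0.62, 0.69, 0.48, 0.50,
                  0.23, 0.24, 0.97, 1.01, 42.53, 43.37),
    nvol_sd   = c(0.01, 0.01, 0.14, 0.11, 0.07, 0.07,
                  0.03, 0.04, 0.14, 0.15, 5.67, 4.98)
  )
}

#' Names of the analysed brain regions of interest
#'
#' Five subcortical structures impaired early in Parkinson's disease plus the
#' cortical gray matter (expected relatively spared at early stages).
#'
#' @return Character vector of six ROI names.
#' @export
brain_rois <- function() {
  c("substantia_nigra", "putamen", "caudate", "pallidum",
    "thalamus", "cortical_gm")
}

# Label-id convention used by the default phantom.
.label_ids <- c(
  white_matter = 1L, csf = 2L, cortical_gm = 3L, substantia_nigra = 4L,
  putamen = 5L, caudate = 6L, pallidum = 7L, thalamus = 8L
)
.tube_label_base <- 100L

#' Define a phantom compartment
#'
#' A compartment couples a label id with ground-truth tissue parameters (TSC
#' and bi-exponential relaxation) and a parametric geometry in voxel
#' coordinates. Geometries are `sphere` / `ellipsoid` (center + radii) or
#' `shell` (ellipsoid minus a concentrically scaled copy). A `fill`
#' compartment claims only the voxels of its shape left unclaimed by other
#' compartments, which emulates carved segmentation labels (e.g. white matter
#' around embedded nuclei).
#'
#' @param label_id Positive integer label, unique within a phantom (0 is
#'   reserved for background).
#' @param name Compartment name.
#' @param true_tsc Ground-truth sodium concentration, mmol/L wet tissue.
#' @param t2_short,t2_long Relaxation times of the fast and slow pools, ms
#'   (`t2_short <= t2_long`).
#' @param short_fraction Signal fraction of the fast pool, in `[0, 1]`.
#' @param geometry List with `type` (`"sphere"`, `"ellipsoid"` or `"shell"`),
#'   `center` (length-3, voxel coordinates), `radii` (length 1 or 3, voxels)
#'   and for shells `inner_scale` in `(0, 1)`.
#' @param fill Logical; claim only unclaimed voxels of the shape (see above).
#' @return A `natsc_compartment` list.
#' @export
compartment <- function(label_id, name, true_tsc, t2_short, t2_long,
                        short_fraction, geometry, fill = FALSE) {
  label_id <- as.integer(label_id)
  if (is.na(label_id) || label_id <= 0L) abort("label_id must be a positive integer")
  if (!is.numeric(true_tsc) || true_tsc < 0) abort("true_tsc must be >= 0")
  if (t2_short <= 0 || t2_long <= 0) abort("relaxation times must be positive")
  if (t2_short > t2_long) abort("t2_short must not exceed t2_long")
  if (short_fraction < 0 || short_fraction > 1) abort("short_fraction must lie in [0, 1]")
  geometry$type <- match.arg(geometry$type, c("sphere", "ellipsoid", "shell"))
  if (length(geometry$radii) == 1L) geometry$radii <- rep(geometry$radii, 3L)
  structure(
    list(label_id = label_id, name = name, true_tsc = true_tsc,
         t2_short = t2_short, t2_long = t2_long,
         short_fraction = short_fraction, geometry = geometry, fill = fill),
    class = "natsc_compartment"
  )
}

#' Assemble a phantom specification
#'
#' @param compartments List of [compartment()] objects: brain tissues plus
#'   exactly six reference tubes (label ids above 100 by convention, set via
#'   `tube_labels`).
#' @param grid_shape Integer length-3, voxels per axis.
#' @param voxel_size Isotropic voxel edge, mm.
#' @param icv_labels Label ids counted as intracranial (brain tissues, not
#'   tubes).
#' @param tube_labels Label ids of the reference tubes.
#' @param signal_per_mmol Global proportionality constant between ground-truth
#'   TSC and the simulated signal ordinate at TE = 0; shared by tissue and
#'   tubes.
#' @return A `natsc_phantom_spec` list.
#' @export
phantom_spec <- function(compartments, grid_shape = c(48L, 48L, 48L),
                         voxel_size = 3, icv_labels, tube_labels,
                         signal_per_mmol = 1) {
  if (length(compartments) == 0L) abort("compartments must be a non-empty list")
  ids <- vapply(compartments, function(co) co$label_id, integer(1))
  if (anyDuplicated(ids)) abort("compartment label_ids must be unique")
  if (length(grid_shape) != 3L || any(grid_shape < 4)) {
    abort("grid_shape must give 3 axes of at least 4 voxels")
  }
  tubes <- compartments[ids %in% tube_labels]
  if (length(tubes) != 6L) abort("a phantom requires exactly six reference tubes")
  conc <- vapply(tubes, function(co) co$true_tsc, numeric(1))
  if (min(conc) < 25 - 1e-9 || max(conc) > 100 + 1e-9) {
    abort("tube concentrations must span the 25-100 mmol/L reference range")
  }
  if (any(icv_labels %in% tube_labels)) abort("tubes cannot be intracranial labels")
  structure(
    list(compartments = compartments, grid_shape = as.integer(grid_shape),
         voxel_size = voxel_size, icv_labels = as.integer(icv_labels),
         tube_labels = as.integer(tube_labels),
         signal_per_mmol = signal_per_mmol),
    class = "natsc_phantom_spec"
  )
}

#' Default head phantom emulating the study acquisition
#'
#' Builds a parametric head phantom on an isotropic grid: an ellipsoidal
#' intracranial volume with a white-matter interior, a cortical gray-matter
#' shell, a central CSF cavity, five embedded subcortical nuclei (substantia
#' nigra, putamen, caudate, pallidum, thalamus), and six reference tubes of
#' known concentration placed inside the field of view but outside the skull.
#' ROI sphere radii and the cortical shell thickness are derived from the
#' requested normalized volumes (% of ICV), so the rendered phantom reproduces
#' the target volume fractions up to voxel quantization.
#'
#' @param group `"iPD"` or `"HC"`; selects the reference group means as
#'   ground-truth TSC and volumes (see [roi_reference_values()]).
#' @param tsc Optional named numeric vector overriding per-ROI ground-truth
#'   TSC (mmol/L); names from [brain_rois()].
#' @param volume_frac Optional named numeric vector overriding per-ROI
#'   normalized volumes (% of ICV).
#' @param grid_shape,voxel_size Grid geometry; defaults 48^3 voxels at 3 mm.
#' @param tube_concentrations Six reference concentrations, mmol/L; default
#'   equally spaced over the 25-100 mmol/L range.
#' @param t2_short,t2_long,short_fraction Default bi-exponential relaxation
#'   parameters shared by tissue and tube compartments (CSF is modeled as a
#'   single slow pool).
#' @param wm_tsc,csf_tsc Ground-truth TSC of white matter and CSF, mmol/L.
#' @param signal_per_mmol See [phantom_spec()].
#' @return A `natsc_phantom_spec`.
#' @examples
#' spec <- default_phantom_spec("iPD", grid_shape = c(24, 24, 24))
#' phantom <- build_phantom(spec, seed = 1)
#' @export
default_phantom_spec <- function(group = c("iPD", "HC"), tsc = NULL,
                                 volume_frac = NULL,
                                 grid_shape = c(48L, 48L, 48L), voxel_size = 3,
                                 tube_concentrations = c(25, 40, 55, 70, 85, 100),
                                 t2_short = 4, t2_long = 35,
                                 short_fraction = 0.6,
                                 wm_tsc = 35, csf_tsc = 140,
                                 signal_per_mmol = 1) {
  group <- match.arg(group)
  ref <- dplyr::filter(roi_reference_values(), .data$group == !!group)
  tsc_map <- setNames(ref$tsc_mean, ref$roi)
  nvol_map <- setNames(ref$nvol_mean, ref$roi)
  if (!is.null(tsc)) {
    check_roi_names(names(tsc))
    tsc_map[names(tsc)] <- tsc
  }
  if (!is.null(volume_frac)) {
    check_roi_names(names(volume_frac))
    nvol_map[names(volume_frac)] <- volume_frac
  }
  if (length(tube_concentrations) != 6L) abort("six tube concentrations are required")

  g <- as.numeric(grid_shape)
  c0 <- (g + 1) / 2
  outer_radii <- g * c(20, 22, 18) / 48
  v_icv <- 4 / 3 * pi * prod(outer_radii)          # analytic ICV, voxels
  roi_radius <- function(frac) (3 / (4 * pi) * frac / 100 * v_icv)^(1 / 3)
  inner_scale <- (1 - nvol_map[["cortical_gm"]] / 100)^(1 / 3)
  off <- function(f) c0 + g * f                    # fractional offset -> voxels

  sphere <- function(center, r) list(type = "sphere", center = center, radii = r)
  roi_sphere <- function(name, frac_off) {
    sphere(off(frac_off), roi_radius(nvol_map[[name]]))
  }
  tissue <- function(label, name, value, geom, fill = FALSE, f = short_fraction,
                     t2s = t2_short, t2l = t2_long) {
    compartment(label, name, value, t2s, t2l, f, geom, fill = fill)
  }

  comps <- list(
    tissue(.label_ids[["white_matter"]], "white_matter", wm_tsc,
           list(type = "ellipsoid", center = c0, radii = inner_scale * outer_radii),
           fill = TRUE),
    tissue(.label_ids[["csf"]], "csf", csf_tsc,
           list(type = "ellipsoid", center = off(c(0, 0, 0.0521)),
                radii = g * c(3, 4, 3) / 48),
           f = 0, t2s = t2_long, t2l = max(t2_long, 55)),
    tissue(.label_ids[["cortical_gm"]], "cortical_gm", tsc_map[["cortical_gm"]],
           list(type = "shell", center = c0, radii = outer_radii,
                inner_scale = inner_scale)),
    tissue(.label_ids[["substantia_nigra"]], "substantia_nigra",
           tsc_map[["substantia_nigra"]],
           roi_sphere("substantia_nigra", c(0, -0.0521, -0.2396))),
    tissue(.label_ids[["putamen"]], "putamen", tsc_map[["putamen"]],
           roi_sphere("putamen", c(0.1771, 0.03125, -0.0521))),
    tissue(.label_ids[["caudate"]], "caudate", tsc_map[["caudate"]],
           roi_sphere("caudate", c(0, 0.1667, 0.0104))),
    tissue(.label_ids[["pallidum"]], "pallidum", tsc_map[["pallidum"]],
           roi_sphere("pallidum", c(-0.1979, -0.0104, -0.0521))),
    tissue(.label_ids[["thalamus"]], "thalamus", tsc_map[["thalamus"]],
           roi_sphere("thalamus", c(0, 0, -0.1146)))
  )

  tube_off <- list(c(-0.3958, -0.3958, 0), c(0.3958, -0.3958, 0),
                   c(-0.3958, 0.3958, 0), c(0.3958, 0.3958, 0),
                   c(0, -0.3958, -0.3958), c(0, 0.3958, 0.3958))
  tube_r <- max(1.05, g[1] * 2.6 / 48)
  tubes <- purrr::imap(sort(tube_concentrations), function(conc, i) {
    tissue(.tube_label_base + i, paste0("tube_", i), conc,
           sphere(off(tube_off[[i]]), tube_r))
  })

  phantom_spec(c(comps, tubes), grid_shape = grid_shape,
               voxel_size = voxel_size, icv_labels = unname(.label_ids),
               tube_labels = .tube_label_base + seq_len(6L),
               signal_per_mmol = signal_per_mmol)
}

check_roi_names <- function(nms) {
  bad <- setdiff(nms, brain_rois())
  if (length(bad) > 0) {
    abort(paste0("unknown ROI name(s): ", paste(bad, collapse = ", ")))
  }
  invisible(nms)
}

#' Tabulate the compartments of a phantom specification
#'
#' @param spec A `natsc_phantom_spec`.
#' @return A tibble, one row per compartment.
#' @export
compartment_table <- function(spec) {
  purrr::map_dfr(spec$compartments, function(co) {
    tibble(label_id = co$label_id, name = co$name, true_tsc = co$true_tsc,
           t2_short = co$t2_short, t2_long = co$t2_long,
           short_fraction = co$short_fraction, shape = co$geometry$type)
  })
}
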
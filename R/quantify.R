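#' Mean fitted signal in each reference tube
#'
#' Averages the fitted signal ordinate `s0` over the converged voxels of each
#' reference tube, pairing it with the tube's known concentration. Tube means
#' are the input of the signal-to-concentration calibration.
#'
#' @param s0_map 3-D array of fitted `s0` values (NA outside the fit mask).
#' @param labels 3-D integer label volume on the same grid.
#' @param tubes Tibble/data frame with columns `label_id` and `concentration`
#'   (mmol/L), one row per tube.
#' @param convergence_mask Optional 3-D logical array; only `TRUE` voxels are
#'   averaged.
#' @return Tibble with columns `concentration`, `mean_s0`, `n_voxels`,
#'   ordered by ascending concentration.
#' @export
tube_mean_signals <- function(s0_map, labels, tubes, convergence_mask = NULL) {
  stopifnot(identical(dim(s0_map), dim(labels)))
  if (is.null(convergence_mask)) convergence_mask <- !is.na(s0_map)
  tubes <- dplyr::arrange(as_tibble(tubes), .data$concentration)
  rows <- purrr::pmap_dfr(tubes, function(label_id, concentration, ...) {
    sel <- labels == label_id & convergence_mask
    if (!any(labels == label_id)) {
      abort(paste0("tube label ", label_id, " absent from label volume"))
    }
    if (!any(sel)) {
      abort(paste0("tube label ", label_id, " has no converged voxels"))
    }
    tibble(concentration = concentration, mean_s0 = mean(s0_map[sel]),
           n_voxels = sum(sel))
  })
  rows
}

#' Calibrate fitted signal against known tube concentrations
#'
#' Ordinary least-squares line `mean_s0 = slope * concentration + intercept`
#' over the reference tubes. With `zero_intercept = TRUE` the line is forced
#' through the origin (a pure proportionality).
#'
#' @param tube_data Tibble with columns `concentration` and `mean_s0` (e.g.
#'   from [tube_mean_signals()]); at least 3 tubes with distinct
#'   concentrations.
#' @param zero_intercept Force the intercept to zero.
#' @return A `natsc_calibration` object with `slope` (signal per mmol/L),
#'   `intercept`, `r_squared` and the `tube_means` table.
#' @export
fit_calibration <- function(tube_data, zero_intercept = FALSE) {
  tube_data <- as_tibble(tube_data)
  conc <- tube_data$concentration
  if (length(conc) < 3L || length(unique(conc)) < 3L) {
    abort("calibration needs at least 3 tubes with distinct concentrations")
  }
  fit <- if (zero_intercept) {
    lm(mean_s0 ~ concentration + 0, data = tube_data)
  } else {
    lm(mean_s0 ~ concentration, data = tube_data)
  }
  cf <- coef(fit)
  slope <- unname(cf[["concentration"]])
  intercept <- if (zero_intercept) 0 else unname(cf[["(Intercept)"]])
  tss <- sum((tube_data$mean_s0 - mean(tube_data$mean_s0))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
  structure(
    list(slope = slope, intercept = intercept,
         r_squared = min(max(r2, 0), 1), tube_means = tube_data,
         zero_intercept = zero_intercept),
    class = "natsc_calibration"
  )
}

#' @export
print.natsc_calibration <- function(x, ...) {
  cat("<natsc_calibration> s0 = ", signif(x$slope, 6), " * conc + ",
      signif(x$intercept, 6), "  (R^2 = ", signif(x$r_squared, 4), ", ",
      nrow(x$tube_means), " tubes)\n", sep = "")
  invisible(x)
}

#' Convert a fitted signal map to absolute sodium concentration
#'
#' Inverts the tube calibration voxelwise: `tsc = (s0 - intercept) / slope`.
#' Negative calibrated values (possible under noise) are clipped to zero and
#' counted.
#'
#' @param s0_map 3-D array of fitted signal ordinates.
#' @param model A `natsc_calibration` with positive slope.
#' @param voxel_size Voxel edge, mm (carried into the result).
#' @return A `natsc_tsc_map` list: `tsc_volume` (mmol/L), `voxel_size`,
#'   `calibration`, `n_clipped`.
#' @export
apply_calibration <- function(s0_map, model, voxel_size = NA_real_) {
  stopifnot(inherits(model, "natsc_calibration"))
  if (!is.finite(model$slope) || model$slope <= 0) {
    abort("calibration slope must be positive")
  }
  tsc <- (s0_map - model$intercept) / model$slope
  neg <- which(tsc < 0)
  tsc[neg] <- 0
  structure(
    list(tsc_volume = tsc, voxel_size = voxel_size, calibration = model,
         n_clipped = length(neg)),
    class = "natsc_tsc_map"
  )
}

#' Per-ROI mean TSC and normalized volume
#'
#' Averages the calibrated concentration over the converged voxels of each
#' requested ROI and reports the ROI volume as a percentage of the
#' intracranial volume (`normalized_volume = 100 * n_voxels /
#' icv_voxel_count`), the head-size normalization used for group comparisons.
#'
#' @param tsc A `natsc_tsc_map` (or a bare 3-D array of concentrations).
#' @param labels 3-D integer label volume.
#' @param roi_set Named integer vector mapping ROI names to label ids;
#'   defaults to the six study ROIs under the default phantom labeling. May
#'   be empty, giving an empty summary.
#' @param icv_voxel_count Total intracranial voxel count (>= 1).
#' @param convergence_mask Optional 3-D logical array of usable voxels.
#' @param subject_id,group Identifiers copied into the output rows.
#' @return Tibble with one row per ROI: `subject_id`, `group`, `roi`,
#'   `mean_tsc`, `voxel_count`, `normalized_volume`.
#' @export
roi_summary <- function(tsc, labels, roi_set = default_roi_set(),
                        icv_voxel_count, convergence_mask = NULL,
                        subject_id = "subject", group = NA_character_) {
  vol <- if (inherits(tsc, "natsc_tsc_map")) tsc$tsc_volume else tsc
  stopifnot(identical(dim(vol), dim(labels)))
  if (icv_voxel_count < 1) abort("icv_voxel_count must be >= 1")
  if (is.null(convergence_mask)) convergence_mask <- !is.na(vol)
  if (length(roi_set) == 0L) {
    return(tibble(subject_id = character(), group = character(),
                  roi = character(), mean_tsc = numeric(),
                  voxel_count = integer(), normalized_volume = numeric()))
  }
  purrr::imap_dfr(roi_set, function(label_id, roi) {
    in_roi <- labels == label_id
    if (!any(in_roi)) abort(paste0("ROI '", roi, "' absent from label volume"))
    usable <- in_roi & convergence_mask
    tibble(
      subject_id = subject_id, group = group, roi = roi,
      mean_tsc = if (any(usable)) mean(vol[usable]) else NA_real_,
      voxel_count = sum(in_roi),
      normalized_volume = 100 * sum(in_roi) / icv_voxel_count
    )
  })
}

#' Default ROI name to label-id mapping of the study phantom
#' @return Named integer vector over [brain_rois()].
#' @export
default_roi_set <- function() {
  .label_ids[brain_rois()]
}
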
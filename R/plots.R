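#' Plot a tube calibration line
#'
#' Tube mean signals against known concentrations with the fitted
#' calibration line; a sanity check that the signal-to-concentration mapping
#' is linear across the 25-100 mmol/L range.
#'
#' @param object A `natsc_calibration`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.natsc_calibration <- function(object, ...) {
  ggplot2::ggplot(object$tube_means,
                  ggplot2::aes(x = .data$concentration, y = .data$mean_s0)) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "tube concentration (mmol/L)",
                  y = "mean fitted s0 (signal units)",
                  title = sprintf("Tube calibration (R² = %.4f)",
                                  object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot a group comparison
#'
#' Group means with SD error bars per ROI, faceted by measure; ROIs whose
#' TSC difference survives Bonferroni correction are starred.
#'
#' @param object A `natsc_group_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.natsc_group_comparison <- function(object, ...) {
  g1 <- object$groups[1]; g2 <- object$groups[2]
  long <- dplyr::bind_rows(
    dplyr::transmute(object$table, roi = .data$roi, measure = .data$measure,
                     group = g1, mean = .data[[paste0("mean_", g1)]],
                     sd = .data[[paste0("sd_", g1)]],
                     sig = .data$significant_after_bonferroni),
    dplyr::transmute(object$table, roi = .data$roi, measure = .data$measure,
                     group = g2, mean = .data[[paste0("mean_", g2)]],
                     sd = .data[[paste0("sd_", g2)]],
                     sig = .data$significant_after_bonferroni)
  )
  long$roi_lab <- ifelse(long$sig, paste0(long$roi, " *"), long$roi)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$roi_lab, y = .data$mean,
                                     colour = .data$group)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "group mean ± SD",
                  caption = "* survives Bonferroni correction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot a voxel decay curve with its bi-exponential fit
#'
#' @param signals Measured signals, one per echo.
#' @param schedule Echo times, ms.
#' @param fit Optional one-row tibble from [fit_voxel()]; fitted curve drawn
#'   when supplied.
#' @return A ggplot.
#' @export
plot_decay <- function(signals, schedule = default_echo_schedule(),
                       fit = NULL) {
  df <- tibble(te = schedule, signal = signals)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$te, y = .data$signal)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "echo time (ms)", y = "signal (a.u.)") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    te_fine <- seq(0, max(schedule), length.out = 200)
    curve <- tibble(te = te_fine,
                    signal = biexp_signal(te_fine, fit$s0, fit$short_fraction,
                                          fit$t2_short, fit$t2_long))
    p <- p + ggplot2::geom_line(data = curve, colour = "grey40")
  }
  p
}

#' Plot an axial slice of a TSC map
#'
#' @param object A `natsc_tsc_map`.
#' @param slice Axial (z) slice index; defaults to the middle slice.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.natsc_tsc_map <- function(object, slice = NULL, ...) {
  d <- dim(object$tsc_volume)
  slice <- slice %||% ceiling(d[3] / 2)
  sl <- object$tsc_volume[, , slice]
  df <- tibble(x = rep(seq_len(d[1]), times = d[2]),
               y = rep(seq_len(d[2]), each = d[1]),
               tsc = as.vector(sl))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$tsc)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "TSC\n(mmol/L)", na.value = "black") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("TSC map, axial slice %d", slice)) +
    ggplot2::theme_void()
}
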
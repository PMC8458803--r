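#' Tidy a tube calibration
#'
#' @param x A `natsc_calibration`.
#' @param ... Unused.
#' @return Tibble with one row per tube: `concentration`, `mean_s0`,
#'   `fitted`, `residual`.
#' @exportS3Method generics::tidy
tidy.natsc_calibration <- function(x, ...) {
  dplyr::mutate(x$tube_means,
                fitted = x$slope * .data$concentration + x$intercept,
                residual = .data$mean_s0 - .data$fitted)
}

#' @rdname tidy.natsc_calibration
#' @return For `glance()`: one-row tibble with `slope`, `intercept`,
#'   `r_squared`, `n_tubes`.
#' @exportS3Method generics::glance
glance.natsc_calibration <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept,
         r_squared = x$r_squared, n_tubes = nrow(x$tube_means),
         zero_intercept = x$zero_intercept)
}

#' Tidy a group comparison
#'
#' @param x A `natsc_group_comparison`.
#' @param ... Unused.
#' @return The per-ROI, per-measure comparison tibble.
#' @exportS3Method generics::tidy
tidy.natsc_group_comparison <- function(x, ...) {
  x$table
}

#' @rdname tidy.natsc_group_comparison
#' @exportS3Method generics::glance
glance.natsc_group_comparison <- function(x, ...) {
  tibble(alpha = x$alpha, n_comparisons = x$n_comparisons,
         corrected_threshold = x$corrected_threshold,
         display_threshold = x$display_threshold,
         n_significant = sum(x$table$significant_after_bonferroni))
}
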
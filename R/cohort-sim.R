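#' Default per-group cohort parameters
#'
#' The reference group means and SDs of TSC and normalized volume per ROI
#' (see [roi_reference_values()]), in the long format accepted by
#' [sample_cohort()].
#'
#' @return Tibble with columns `roi`, `group`, `tsc_mean`, `tsc_sd`,
#'   `nvol_mean`, `nvol_sd`.
#' @export
default_group_params <- function() {
  roi_reference_values()
}

# One truncated-normal draw per cell: Gaussian, resampled below zero.
rtruncnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  bad <- which(x < 0)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < 0]
  }
  x
}

#' Draw a synthetic cohort with known per-subject ground truth
#'
#' Samples per-subject, per-ROI ground-truth TSC and normalized volume
#' independently from each group's Gaussian (truncated at 0), using the study
#' design of 10 patients (`iPD`) and 12 healthy controls (`HC`) by default.
#' The draw is seeded per subject, so changing cohort sizes leaves earlier
#' subjects' values unchanged.
#'
#' @param group_params Long tibble of per-group parameters (see
#'   [default_group_params()]); ROI names must belong to [brain_rois()].
#' @param n_ipd,n_hc Group sizes (>= 1).
#' @param seed Master seed.
#' @return Long tibble: `subject_id`, `group`, `roi`, `tsc`, `nvol` —
#'   one row per subject x ROI.
#' @examples
#' cohort <- sample_cohort(seed = 7)
#' dplyr::count(cohort, group) # 6 rows per subject
#' @export
sample_cohort <- function(group_params = default_group_params(),
                          n_ipd = 10L, n_hc = 12L, seed = 1L) {
  if (n_ipd < 1 || n_hc < 1) abort("group sizes must be >= 1")
  group_params <- as_tibble(group_params)
  check_roi_names(unique(group_params$roi))
  if (any(group_params$tsc_sd < 0) || any(group_params$nvol_sd < 0)) {
    abort("standard deviations must be >= 0")
  }

  subjects <- tibble(
    subject_id = c(sprintf("iPD%02d", seq_len(n_ipd)),
                   sprintf("HC%02d", seq_len(n_hc))),
    group = rep(c("iPD", "HC"), c(n_ipd, n_hc))
  )

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)

  purrr::pmap_dfr(subjects, function(subject_id, group) {
    pars <- dplyr::filter(group_params, .data$group == !!group)
    if (nrow(pars) == 0) abort(paste0("no parameters for group ", group))
    set.seed(derive_seed(seed, "cohort", subject_id))
    tibble(
      subject_id = subject_id, group = group, roi = pars$roi,
      tsc = vapply(seq_len(nrow(pars)), function(i) {
        rtruncnorm0(1, pars$tsc_mean[i], pars$tsc_sd[i])
      }, numeric(1)),
      nvol = vapply(seq_len(nrow(pars)), function(i) {
        rtruncnorm0(1, pars$nvol_mean[i], pars$nvol_sd[i])
      }, numeric(1))
    )
  })
}
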
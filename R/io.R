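#' Write a 3-D or 4-D volume as NIfTI-1
#'
#' @param vol Numeric or integer array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size Isotropic voxel edge, mm, recorded in the header.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, voxel_size = 1) {
  img <- RNifti::asNifti(vol)
  pd <- RNifti::pixdim(img)
  pd[seq_len(min(3L, length(pd)))] <- voxel_size
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path NIfTI file path.
#' @return List with `data` (array) and `voxel_size` (mm, first pixdim).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = as.array(img), voxel_size = RNifti::pixdim(img)[1])
}

#' Write a cohort table as the wide per-subject CSV
#'
#' One row per subject; per-ROI columns `<roi>_tsc` and `<roi>_nvol`.
#'
#' @param cohort Long tibble (`subject_id`, `group`, `roi`, `tsc`, `nvol`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  wide <- tidyr::pivot_wider(
    dplyr::select(as_tibble(cohort), "subject_id", "group", "roi",
                  "tsc", "nvol"),
    names_from = "roi", values_from = c("tsc", "nvol"),
    names_glue = "{roi}_{.value}"
  )
  readr::write_csv(wide, path)
  invisible(path)
}

#' Read a wide per-subject cohort CSV back into the long format
#'
#' @param path CSV written by [write_cohort_csv()].
#' @return Long tibble (`subject_id`, `group`, `roi`, `tsc`, `nvol`).
#' @export
read_cohort_csv <- function(path) {
  wide <- readr::read_csv(path, show_col_types = FALSE)
  long <- tidyr::pivot_longer(wide, cols = -c("subject_id", "group"),
                              names_to = c("roi", "measure"),
                              names_pattern = "(.*)_(tsc|nvol)$")
  tidyr::pivot_wider(long, names_from = "measure", values_from = "value")
}
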
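# Deterministic child seed from a master seed, stage tag and index.
# Keeps results reproducible per subject/stage while staying below 2^31.
derive_seed <- function(master, stage, index = 0L) {
  h <- as.double(master) %% 2147483647
  for (ch in utf8ToInt(paste0(stage, ":", index))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# Separable 3-D Gaussian blur; sigma in voxels, truncated at 3 sigma.
gaussian_blur3 <- function(vol, sigma) {
  if (sigma <= 0) return(vol)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(vol)
  conv_axis <- function(v, axis) {
    # bring target axis first, convolve columns with renormalized edge kernel
    perm <- c(axis, setdiff(1:3, axis))
    m <- matrix(aperm(v, perm), nrow = d[axis])
    n <- nrow(m)
    band <- matrix(0, n, n)
    for (j in seq(-r, r)) {
      idx <- seq_len(n)
      keep <- idx + j >= 1 & idx + j <= n
      band[cbind(idx[keep] + j, idx[keep])] <- k[j + r + 1]
    }
    band <- sweep(band, 2, colSums(band), "/")  # renormalize at edges
    out <- band %*% m
    aperm(array(out, d[perm]), order(perm))
  }
  for (axis in 1:3) vol <- conv_axis(vol, axis)
  vol
}

#' Simulate multi-echo sodium magnitude images from a phantom
#'
#' Evaluates the bi-exponential decay model at every echo time using each
#' voxel's ground-truth relaxation parameters, with the signal ordinate at
#' TE = 0 proportional to the ground-truth TSC through the single global
#' constant `spec$signal_per_mmol` (shared by tissue and reference tubes).
#' An optional isotropic Gaussian blur emulates the point-spread function of
#' the acquisition, after which Rician noise (magnitude of complex Gaussian
#' noise) is applied, as appropriate for magnitude MR images.
#'
#' @param phantom A `natsc_phantom` from [build_phantom()].
#' @param schedule Echo times, ms; default [default_echo_schedule()].
#' @param noise_sd Standard deviation of each complex Gaussian noise channel,
#'   in signal units; 0 disables noise.
#' @param blur_fwhm Full width at half maximum of the Gaussian blur, mm; 0
#'   disables blurring.
#' @param seed Integer seed; simulation is bit-reproducible for a fixed
#'   (phantom, schedule, noise_sd, blur_fwhm, seed).
#' @return A `natsc_multiecho` list: `data` (4-D array, x-y-z-echo),
#'   `schedule`, `voxel_size`.
#' @export
simulate_multiecho <- function(phantom, schedule = default_echo_schedule(),
                               noise_sd = 0, blur_fwhm = 0, seed = 1L) {
  stopifnot(inherits(phantom, "natsc_phantom"))
  validate_echo_schedule(schedule)
  if (!is.numeric(noise_sd) || noise_sd < 0) abort("noise_sd must be >= 0")
  if (blur_fwhm < 0) abort("blur_fwhm must be >= 0")

  d <- dim(phantom$label_volume)
  n_te <- length(schedule)
  k <- phantom$spec$signal_per_mmol
  data <- array(0, c(d, n_te))

  params <- phantom$truth_params
  nz <- which(phantom$label_volume > 0)
  vox_by_label <- split(nz, factor(phantom$label_volume[nz],
                                   levels = params$label_id))

  plane <- prod(d)
  for (i in seq_len(nrow(params))) {
    idx <- vox_by_label[[as.character(params$label_id[i])]]
    if (length(idx) == 0) next
    s0 <- k * params$true_tsc[i]
    decay <- biexp_signal(schedule, s0, params$short_fraction[i],
                          params$t2_short[i], params$t2_long[i])
    for (j in seq_len(n_te)) data[idx + (j - 1) * plane] <- decay[j]
  }

  if (blur_fwhm > 0) {
    sigma_vox <- blur_fwhm / (2 * sqrt(2 * log(2))) / phantom$voxel_size
    for (j in seq_len(n_te)) {
      data[, , , j] <- gaussian_blur3(data[, , , j], sigma_vox)
    }
  }

  if (noise_sd > 0) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(derive_seed(seed, "rician"))
    n <- length(data)
    data <- sqrt((data + rnorm(n, 0, noise_sd))^2 + rnorm(n, 0, noise_sd)^2)
    data <- array(data, c(d, n_te))
  }

  structure(list(data = data, schedule = schedule,
                 voxel_size = phantom$voxel_size),
            class = "natsc_multiecho")
}

# Save/restore the global RNG state so simulation seeds stay self-contained.
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_set <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' @export
print.natsc_multiecho <- function(x, ...) {
  d <- dim(x$data)
  cat("<natsc_multiecho> ", paste(d[1:3], collapse = " x "), " voxels, ",
      d[4], " echoes (", min(x$schedule), "-", max(x$schedule), " ms) at ",
      x$voxel_size, " mm\n", sep = "")
  invisible(x)
}
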
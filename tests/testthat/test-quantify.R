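make_tube_volume <- function() {
  labels <- array(0L, c(6, 6, 6))
  s0 <- array(NA_real_, c(6, 6, 6))
  for (i in 1:6) {
    labels[i, 1:2, 1] <- 100L + i
    s0[i, 1:2, 1] <- 2 * c(25, 40, 55, 70, 85, 100)[i]
  }
  list(labels = labels, s0 = s0,
       tubes = tibble::tibble(label_id = 101:106,
                              concentration = c(25, 40, 55, 70, 85, 100)))
}

test_that("tube means average converged voxels per tube, ordered by concentration", {
  v <- make_tube_volume()
  tm <- tube_mean_signals(v$s0, v$labels, v$tubes)
  expect_equal(nrow(tm), 6)
  expect_equal(tm$concentration, c(25, 40, 55, 70, 85, 100))
  expect_equal(tm$mean_s0, 2 * tm$concentration)
  expect_equal(tm$n_voxels, rep(2L, 6))

  # missing tube label and fully non-converged tube are errors
  expect_error(tube_mean_signals(v$s0, v$labels,
                                 rbind(v$tubes, list(label_id = 120L,
                                                     concentration = 30))),
               "120")
  conv <- array(TRUE, dim(v$s0))
  conv[v$labels == 103L] <- FALSE
  expect_error(tube_mean_signals(v$s0, v$labels, v$tubes, conv), "103")
})

test_that("calibration recovers a known line exactly", {
  conc <- c(25, 40, 55, 70, 85, 100)
  # closed-form least-squares oracle
  ols <- function(x, y) {
    b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    c(slope = b, intercept = mean(y) - b * mean(x))
  }

  cal <- fit_calibration(tibble::tibble(concentration = conc,
                                        mean_s0 = 2 * conc))
  expect_equal(cal$slope, 2)
  expect_equal(cal$intercept, 0)
  expect_equal(cal$r_squared, 1)

  y <- 1.37 * conc + 4.2
  cal2 <- fit_calibration(tibble::tibble(concentration = conc, mean_s0 = y))
  oracle <- ols(conc, y)
  expect_equal(cal2$slope, unname(oracle["slope"]), tolerance = 1e-12)
  expect_equal(cal2$intercept, unname(oracle["intercept"]), tolerance = 1e-12)

  # noisy line still matches the closed-form OLS oracle
  set.seed(8)
  yn <- y + rnorm(6, 0, 3)
  cal3 <- fit_calibration(tibble::tibble(concentration = conc, mean_s0 = yn))
  oracle3 <- ols(conc, yn)
  expect_equal(cal3$slope, unname(oracle3["slope"]), tolerance = 1e-12)
  expect_equal(cal3$intercept, unname(oracle3["intercept"]), tolerance = 1e-12)

  zi <- fit_calibration(tibble::tibble(concentration = conc, mean_s0 = 2 * conc),
                        zero_intercept = TRUE)
  expect_equal(zi$intercept, 0)
  expect_equal(zi$slope, 2)

  expect_error(fit_calibration(tibble::tibble(concentration = c(25, 40),
                                              mean_s0 = c(1, 2))), "3 tubes")
  expect_error(fit_calibration(tibble::tibble(concentration = rep(50, 6),
                                              mean_s0 = 1:6)), "distinct")
})

test_that("applying a calibration inverts the tube mapping", {
  v <- make_tube_volume()
  tm <- tube_mean_signals(v$s0, v$labels, v$tubes)
  cal <- fit_calibration(tm)
  tsc <- apply_calibration(v$s0, cal)

  # inverse consistency on the tube means themselves
  for (i in 1:6) {
    vox <- v$labels == 100L + i
    expect_equal(mean(tsc$tsc_volume[vox]), tm$concentration[i],
                 tolerance = 1e-9)
  }

  # s0 == intercept maps to 0; negatives clip to 0 and are counted
  shifted <- structure(list(slope = 2, intercept = 10, r_squared = 1,
                            tube_means = tm, zero_intercept = FALSE),
                       class = "natsc_calibration")
  m <- apply_calibration(array(c(10, 4, 30), c(3, 1, 1)), shifted)
  expect_equal(as.vector(m$tsc_volume), c(0, 0, 10))
  expect_equal(m$n_clipped, 1L)

  bad <- shifted; bad$slope <- -1
  expect_error(apply_calibration(v$s0, bad), "slope")
})

test_that("ROI summaries compute means and ICV-normalized volumes", {
  labels <- array(0L, c(50, 50, 40))
  labels[1:10, 1:7, 1] <- 4L           # 70-voxel "SN"
  tsc <- array(NA_real_, dim(labels))
  tsc[labels == 4L] <- 43.73
  rs <- roi_summary(tsc, labels, roi_set = c(substantia_nigra = 4L),
                    icv_voxel_count = 100000)
  expect_equal(rs$mean_tsc, 43.73)
  expect_equal(rs$voxel_count, 70L)
  expect_equal(rs$normalized_volume, 0.07)

  expect_equal(nrow(roi_summary(tsc, labels, roi_set = integer(0),
                                icv_voxel_count = 1)), 0)
  expect_error(roi_summary(tsc, labels, roi_set = c(putamen = 5L),
                           icv_voxel_count = 100), "putamen")

  # deleting voxels outside the ROI does not change its mean
  tsc2 <- tsc
  tsc2[labels == 0L] <- NA_real_
  rs2 <- roi_summary(tsc2, labels, roi_set = c(substantia_nigra = 4L),
                     icv_voxel_count = 100000)
  expect_equal(rs2$mean_tsc, rs$mean_tsc)
})

test_that("noiseless end-to-end run recovers every ROI mean within 0.25%", {
  rs <- roundtrip_summary(small_spec("iPD"))
  truth <- table2_tsc("iPD")
  rel <- abs(rs$mean_tsc - truth[rs$roi]) / truth[rs$roi]
  expect_lt(max(rel), 0.0025)

  # tube means proportional to concentration with a uniform constant
  ph <- build_phantom(small_spec("iPD"))
  img <- simulate_multiecho(ph, noise_sd = 0)
  maps <- fit_volume(img, ph$label_volume > 0L)
  tm <- tube_mean_signals(maps$s0_map, ph$label_volume,
                          tibble::tibble(label_id = ph$spec$tube_labels,
                                         concentration = c(25, 40, 55, 70, 85, 100)),
                          maps$convergence_mask)
  ratio <- tm$mean_s0 / tm$concentration
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-6)
})

test_that("noisy end-to-end run stays within 5% at 5%-of-peak-tissue noise", {
  # noise referenced to the peak brain-tissue signal (cortical GM S0);
  # three seeded replicates at the full 48^3 grid, judged on the replicate mean
  spec <- default_phantom_spec("iPD")
  noise <- 0.05 * max(table2_tsc("iPD")) * spec$signal_per_mmol
  reps <- sapply(c(101, 102, 103), function(s) {
    rs <- roundtrip_summary(spec, noise_sd = noise, seed = s)
    stats::setNames(rs$mean_tsc, rs$roi)
  })
  truth <- table2_tsc("iPD")
  rel <- abs(rowMeans(reps) - truth[rownames(reps)]) / truth[rownames(reps)]
  expect_lt(max(rel), 0.05)
})

test_that("normalized volumes are invariant to global intensity scaling", {
  spec <- small_spec("HC")
  ph <- build_phantom(spec)
  img <- simulate_multiecho(ph, noise_sd = 0)
  img2 <- img
  img2$data <- img$data * 5

  get_nvol <- function(image) {
    maps <- fit_volume(image, ph$label_volume > 0L)
    tubes <- tibble::tibble(label_id = spec$tube_labels,
                            concentration = c(25, 40, 55, 70, 85, 100))
    cal <- fit_calibration(tube_mean_signals(maps$s0_map, ph$label_volume,
                                             tubes, maps$convergence_mask))
    tsc <- apply_calibration(maps$s0_map, cal)
    rs <- roi_summary(tsc, ph$label_volume,
                      icv_voxel_count = sum(ph$label_volume %in% spec$icv_labels),
                      convergence_mask = maps$convergence_mask)
    rs$normalized_volume
  }
  expect_equal(get_nvol(img2), get_nvol(img))
})
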
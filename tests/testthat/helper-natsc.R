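# Shared fixtures and oracles for the test suite. Everything is generated in
# code; no binary fixtures.

# Small phantom for fast end-to-end tests (SN still renders >= 1 voxel here).
small_spec <- function(group = "iPD", n = 24L, ...) {
  default_phantom_spec(group, grid_shape = rep(n, 3L), ...)
}

table2_tsc <- function(group = "iPD") {
  ref <- roi_reference_values()
  stats::setNames(ref$tsc_mean[ref$group == group], ref$roi[ref$group == group])
}

# Independent closed-form evaluation of the two-pool decay (used as the
# arithmetic oracle against biexp_signal and the fitters).
oracle_decay <- function(te, s0, f, t2s, t2l) {
  s0 * f * exp(-te / t2s) + s0 * (1 - f) * exp(-te / t2l)
}

# Exhaustive rank-sum oracle: enumerate all assignments of n_a ranks.
oracle_rank_sum_p <- function(a, b) {
  n_a <- length(a)
  n <- n_a + length(b)
  r <- rank(c(a, b))
  w <- sum(r[seq_len(n_a)])
  sums <- utils::combn(n, n_a, FUN = sum)
  min(1, 2 * min(mean(sums <= w), mean(sums >= w)))
}

# Fisher oracle from explicit binomial-coefficient products (independent of
# dhyper): P(a = k) = C(r1, k) C(r2, c1 - k) / C(n, c1).
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, c1 - r2):min(r1, c1)
  pr <- choose(r1, ks) * choose(r2, c1 - ks) / choose(n, c1)
  p_obs <- choose(r1, tab[1, 1]) * choose(r2, c1 - tab[1, 1]) / choose(n, c1)
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

# Run one noiseless subject end-to-end and return the ROI summary tibble.
roundtrip_summary <- function(spec, noise_sd = 0, seed = 1) {
  phantom <- build_phantom(spec)
  image <- simulate_multiecho(phantom, noise_sd = noise_sd, seed = seed)
  maps <- fit_volume(image, phantom$label_volume > 0L)
  tubes <- tibble::tibble(label_id = spec$tube_labels,
                          concentration = c(25, 40, 55, 70, 85, 100))
  calib <- fit_calibration(tube_mean_signals(maps$s0_map, phantom$label_volume,
                                             tubes, maps$convergence_mask))
  tsc <- apply_calibration(maps$s0_map, calib)
  roi_summary(tsc, phantom$label_volume,
              icv_voxel_count = sum(phantom$label_volume %in% spec$icv_labels),
              convergence_mask = maps$convergence_mask)
}

# Null-model cohort simulation shared by the type-I-error and family-wise
# error tests; memoised so the 500 replicates run once per session.
null_sim_env <- new.env(parent = emptyenv())
null_simulation <- function(n_rep = 500L, seed = 20260923L) {
  key <- paste0("r", n_rep, "s", seed)
  if (!is.null(null_sim_env[[key]])) return(null_sim_env[[key]])
  params <- roi_reference_values()
  hc <- params[params$group == "HC", ]
  null_params <- rbind(hc, transform(hc, group = "iPD"))
  res <- lapply(seq_len(n_rep), function(i) {
    cohort <- sample_cohort(null_params, n_ipd = 10, n_hc = 12,
                            seed = seed + i)
    tidy(compare_groups(cohort))
  })
  null_sim_env[[key]] <- res
  res
}
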
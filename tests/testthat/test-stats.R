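test_that("exact rank-sum p equals the enumeration oracle", {
  # frozen textbook case: 20 equally likely splits, extreme observed
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6)), 0.1)

  set.seed(14)
  sizes <- list(c(3, 3), c(4, 5), c(5, 7), c(6, 6), c(2, 9))
  for (sz in sizes) {
    pool <- sample(1000, sum(sz))   # unique values, no ties
    a <- pool[seq_len(sz[1])]
    b <- pool[-seq_len(sz[1])]
    expect_equal(rank_sum_test(a, b), oracle_rank_sum_p(a, b))
    # symmetry and agreement with the reference implementation
    expect_equal(rank_sum_test(b, a), rank_sum_test(a, b))
    expect_equal(rank_sum_test(a, b),
                 stats::wilcox.test(a, b, exact = TRUE)$p.value)
  }
})

test_that("exact rank-sum p is invariant to monotone transforms", {
  set.seed(3)
  a <- runif(5); b <- runif(6)
  p0 <- rank_sum_test(a, b)
  expect_equal(rank_sum_test(exp(a), exp(b)), p0)
  expect_equal(rank_sum_test(a^3 + 7, b^3 + 7), p0)
})

test_that("identical samples give p = 1 and ties use the corrected approximation", {
  x <- c(2, 5, 9)
  expect_equal(rank_sum_test(x, x), 1)

  set.seed(21)
  a <- sample(1:6, 15, replace = TRUE)   # heavy ties, large n -> approx path
  b <- sample(2:7, 14, replace = TRUE)
  expect_equal(rank_sum_test(a, b),
               stats::wilcox.test(a, b, exact = FALSE,
                                  correct = TRUE)$p.value,
               tolerance = 1e-12)
  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("Fisher exact p matches hypergeometric enumeration exhaustively", {
  # printed cohort sex table: 8M/2F patients vs 6M/6F controls
  expect_equal(round(fisher_exact(matrix(c(8, 2, 6, 6), 2, byrow = TRUE)), 2),
               0.20)
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2)), 1)

  # exhaustive sweep over all 2x2 tables with total <= 40
  worst <- 0
  n_tables <- 0L
  for (n in 2:40) {
    for (r1 in 1:(n - 1)) {
      for (c1 in 1:(n - 1)) {
        for (a in max(0, r1 + c1 - n):min(r1, c1)) {
          tab <- matrix(c(a, r1 - a, c1 - a, n - r1 - c1 + a), 2, byrow = TRUE)
          worst <- max(worst, abs(fisher_exact(tab) - oracle_fisher_p(tab)))
          n_tables <- n_tables + 1L
        }
      }
    }
  }
  expect_gt(n_tables, 100000)
  expect_lt(worst, 1e-12)
})

test_that("Fisher preconditions are enforced", {
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2)), "nonnegative")
  expect_error(fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "margins")
  expect_error(fisher_exact(matrix(1:6, 2)), "2x2")
})

test_that("chi-square statistic matches hand computation and the reference", {
  tab <- matrix(c(12, 7, 9, 5, 8, 11), nrow = 2, byrow = TRUE)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat_by_hand <- sum((tab - e)^2 / e)
  res <- chi2_test(tab)
  expect_equal(res$statistic, stat_by_hand)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, pchisq(stat_by_hand, 2, lower.tail = FALSE))

  ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, unname(ref$p.value))

  # a table equal to its own expected table has statistic 0, p = 1
  even <- matrix(c(10, 10, 10, 10), 2)
  expect_equal(chi2_test(even)$statistic, 0)
  expect_equal(chi2_test(even)$p_value, 1)
  expect_error(chi2_test(matrix(c(0, 0, 1, 2), 2, byrow = TRUE)), "margins")
})

test_that("Spearman correlation handles monotone, tied and exact cases", {
  x <- c(1, 3, 4, 7, 9, 12, 15, 20, 21, 30)
  expect_equal(spearman_cor(x, x^3 + 2)$rho, 1)
  expect_equal(spearman_cor(x, rev(x))$rho, -1)

  # tied data: rho equals the Pearson correlation of midranks
  xt <- c(1, 2, 2, 4, 5, 5, 5, 8, 9, 10)
  yt <- c(3, 3, 6, 6, 7, 9, 9, 12, 15, 15)
  expect_equal(spearman_cor(xt, yt)$rho,
               stats::cor(rank(xt), rank(yt)))

  # exact permutation p for small n matches the reference exact method
  set.seed(6)
  xs <- sample(100, 7); ys <- sample(100, 7)
  got <- spearman_cor(xs, ys)
  expect_equal(got$method, "exact")
  ref <- stats::cor.test(xs, ys, method = "spearman", exact = TRUE)
  expect_equal(got$rho, unname(ref$estimate))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)

  # large-n t approximation against the reference
  set.seed(7)
  xl <- rnorm(40); yl <- 0.5 * xl + rnorm(40)
  gl <- spearman_cor(xl, yl)
  rl <- stats::cor.test(xl, yl, method = "spearman", exact = FALSE)
  expect_equal(gl$rho, unname(rl$estimate))
  expect_equal(gl$p_value, rl$p.value, tolerance = 1e-10)

  cst <- spearman_cor(rep(5, 10), rnorm(10))
  expect_false(cst$defined)
  expect_true(is.na(cst$rho))
  expect_error(spearman_cor(1:2, 1:2), "3 paired")
})

test_that("Bonferroni thresholding matches the study display and is monotone", {
  b <- bonferroni(0.05, 6)
  expect_equal(b$display_threshold, 0.008)
  expect_equal(b$corrected_threshold, 0.05 / 6)
  expect_equal(bonferroni(0.05, 1)$corrected_threshold, 0.05)

  set.seed(11)
  for (i in 1:20) {
    p <- runif(6)
    f_hi <- bonferroni(0.05, 6, p)$flags
    f_lo <- bonferroni(0.01, 6, p)$flags
    expect_true(all(!f_hi[!f_hi] | TRUE))   # vacuous guard
    expect_true(all(f_lo <= f_hi))          # lowering alpha never adds flags
  }
  expect_error(bonferroni(0.05, 0), "positive")
  expect_error(bonferroni(1.2, 6), "alpha")
  expect_error(bonferroni(0.05, 6, c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("compare_groups reports per-ROI measures with a TSC-only family", {
  cohort <- sample_cohort(seed = 31)
  cmp <- compare_groups(cohort)
  tab <- tidy(cmp)
  expect_equal(nrow(tab), 12)                    # 6 ROIs x 2 measures
  expect_setequal(unique(tab$roi), brain_rois())
  expect_equal(cmp$n_comparisons, 6)             # TSC family only
  expect_true(all(!tab$significant_after_bonferroni[tab$measure == "nvol"]))
  expect_equal(tab$significant_after_bonferroni,
               tab$in_family & tab$p_uncorrected < 0.05 / 6)

  g <- glance(cmp)
  expect_equal(g$display_threshold, 0.008)

  one <- compare_groups(cohort, measures = "tsc")
  expect_equal(nrow(tidy(one)), 6)

  tiny <- dplyr::filter(cohort, subject_id %in% c("iPD01", "HC01", "HC02"))
  expect_error(compare_groups(tiny), "2 subjects")
})

test_that("a strong SN group difference is detected after correction", {
  params <- roi_reference_values()
  cohort <- sample_cohort(params, n_ipd = 200, n_hc = 200, seed = 17)
  tab <- tidy(compare_groups(cohort))
  sn <- tab[tab$roi == "substantia_nigra" & tab$measure == "tsc", ]
  expect_true(sn$significant_after_bonferroni)
})

test_that("type-I error of the uncorrected tests is nominal under the null", {
  runs <- null_simulation()
  tsc_p <- sapply(runs, function(tab) {
    stats::setNames(tab$p_uncorrected[tab$measure == "tsc"],
                    tab$roi[tab$measure == "tsc"])
  })
  frac <- rowMeans(tsc_p < 0.05)
  expect_true(all(frac >= 0.03 & frac <= 0.07))
})
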
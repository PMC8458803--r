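#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Unpaired two-sample comparison on pooled ranks. With a combined sample
#' size of at most 12 and no ties, the exact null distribution of the rank
#' sum is enumerated over all equally likely group assignments and the
#' two-sided p is twice the smaller tail probability (capped at 1).
#' Otherwise the normal approximation is used, with midrank tie correction
#' of the variance and a 0.5 continuity correction.
#'
#' @param a,b Numeric samples, each non-empty.
#' @return Two-sided p-value.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6)) # exact: 0.1
#' @export
rank_sum_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) abort("both samples must be non-empty")
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  pooled <- c(a, b)
  r <- rank(pooled)
  w <- sum(r[seq_len(n_a)])
  ties <- any(duplicated(pooled))

  if (n <= 12 && !ties) {
    sums <- combn(n, n_a, FUN = function(ix) sum(ix))
    p_lo <- mean(sums <= w)
    p_hi <- mean(sums >= w)
    return(min(1, 2 * min(p_lo, p_hi)))
  }

  mu <- n_a * (n + 1) / 2
  tie_counts <- table(pooled)
  tie_term <- sum(tie_counts^3 - tie_counts) / (n * (n - 1))
  sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  z <- (abs(w - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  min(1, 2 * pnorm(-z))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Sums the hypergeometric probabilities of all tables with the observed
#' margins whose probability does not exceed that of the observed table
#' (the usual two-sided convention).
#'
#' @param table 2x2 matrix of nonnegative integer counts with positive
#'   margins.
#' @return Two-sided p-value.
#' @examples
#' fisher_exact(matrix(c(8, 2, 6, 6), nrow = 2, byrow = TRUE)) # ~0.204
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!identical(dim(table), c(2L, 2L))) abort("a 2x2 table is required")
  if (any(table < 0) || any(table != round(table))) {
    abort("counts must be nonnegative integers")
  }
  r1 <- sum(table[1, ]); c1 <- sum(table[, 1]); n <- sum(table)
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) {
    abort("both margins must be positive")
  }
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  p_obs <- dhyper(table[1, 1], c1, n - c1, r1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Pearson chi-square test of independence
#'
#' Pearson's statistic on an r x c contingency table with
#' `(r - 1)(c - 1)` degrees of freedom, without continuity correction.
#' The pipeline convention is to fall back to [fisher_exact()] whenever an
#' expected count is below 5 (see [expected_counts()]).
#'
#' @param table Matrix of nonnegative counts; all row and column margins must
#'   be positive.
#' @return List with `statistic`, `df`, `p_value`, `expected`.
#' @export
chi2_test <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) abort("counts must be nonnegative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("all margins must be positive")
  }
  e <- expected_counts(table)
  stat <- sum((table - e)^2 / e)
  df <- (nrow(table) - 1) * (ncol(table) - 1)
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE), expected = e)
}

#' Expected counts of a contingency table under independence
#' @param table Matrix of counts.
#' @return Matrix of expected counts.
#' @export
expected_counts <- function(table) {
  table <- as.matrix(table)
  outer(rowSums(table), colSums(table)) / sum(table)
}

#' Spearman rank correlation
#'
#' Rank correlation with midranks for ties. For n <= 8 with no ties in
#' either variable the p-value is exact, from full enumeration of the
#' permutation null distribution of rho; otherwise the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom is
#' used. A constant input vector leaves rho undefined: the result is flagged
#' (`defined = FALSE`) so callers can exclude it from reports.
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @return List with `rho`, `p_value`, `n`, `method`, `defined`.
#' @export
spearman_cor <- function(x, y) {
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (length(y) != n) abort("x and y must have equal length")
  if (n < 3) abort("at least 3 paired observations are required")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                method = "undefined", defined = FALSE))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  ties <- any(duplicated(x)) || any(duplicated(y))

  if (n <= 8 && !ties) {
    perms <- all_permutations(n)
    null_rho <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(null_rho) >= abs(rho) - 1e-12)
    return(list(rho = rho, p_value = p, n = n, method = "exact",
                defined = TRUE))
  }
  if (abs(rho) >= 1) {
    return(list(rho = sign(rho), p_value = 0, n = n, method = "t-approx",
                defined = TRUE))
  }
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p_value = 2 * pt(-abs(tval), n - 2), n = n,
       method = "t-approx", defined = TRUE)
}

# All permutations of 1..n as a matrix (n! rows); n <= 8 keeps this small.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(pos) {
    cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
          sub[, seq_len(n - pos) + pos - 1L, drop = FALSE])
  }))
}

#' Bonferroni family-wise error control
#'
#' Divides the significance level by the number of comparisons and flags
#' p-values strictly below the corrected threshold. The threshold is also
#' reported rounded to 3 decimals for display (0.05 over 6 comparisons
#' displays as 0.008).
#'
#' @param alpha Family-wise significance level in (0, 1).
#' @param m Number of comparisons (>= 1).
#' @param pvalues Optional vector of p-values in `[0, 1]` to flag.
#' @return List with `corrected_threshold` (exact `alpha / m`),
#'   `display_threshold` (rounded to 3 decimals), and `flags` (logical,
#'   present when `pvalues` given).
#' @examples
#' bonferroni(0.05, 6)$display_threshold # 0.008
#' @export
bonferroni <- function(alpha, m, pvalues = NULL) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("alpha must lie in (0, 1)")
  }
  if (!is.numeric(m) || m < 1) abort("m must be a positive integer")
  thr <- alpha / m
  out <- list(corrected_threshold = thr,
              display_threshold = round(thr, 3))
  if (!is.null(pvalues)) {
    if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
      abort("p-values must lie in [0, 1]")
    }
    out$flags <- !is.na(pvalues) & pvalues < thr
  }
  out
}

#' Group comparison battery over ROI measures
#'
#' For every ROI and measure, compares the two groups with the two-sided
#' Wilcoxon rank-sum test and reports group means and SDs. Bonferroni
#' control is applied across the TSC comparisons (one family over the six
#' ROIs); normalized-volume comparisons are reported uncorrected, mirroring
#' a design where only the concentration family is multiplicity-controlled.
#'
#' @param cohort Long-format tibble with columns `subject_id`, `group`
#'   (two levels) and one column per measure, plus `roi`.
#' @param alpha Family-wise significance level; default 0.05.
#' @param measures Character vector of measure columns to compare; default
#'   `c("tsc", "nvol")`.
#' @param corrected_measures Measures entering the Bonferroni family;
#'   default `"tsc"`.
#' @return A `natsc_group_comparison` object; `tidy()` returns the per-ROI
#'   comparison table, `glance()` the family summary.
#' @export
compare_groups <- function(cohort, alpha = 0.05,
                           measures = c("tsc", "nvol"),
                           corrected_measures = "tsc") {
  cohort <- as_tibble(cohort)
  groups <- unique(cohort$group)
  if (length(groups) != 2L) abort("cohort must contain exactly two groups")
  n_by_group <- dplyr::count(dplyr::distinct(cohort, .data$subject_id, .data$group),
                             .data$group)
  if (any(n_by_group$n < 2)) abort("each group needs at least 2 subjects")
  measures <- intersect(measures, names(cohort))
  if (length(measures) == 0L) abort("no requested measure column is present")
  g1 <- groups[1]; g2 <- groups[2]

  rows <- purrr::map_dfr(unique(cohort$roi), function(r) {
    sub <- dplyr::filter(cohort, .data$roi == r)
    purrr::map_dfr(measures, function(m) {
      v1 <- sub[[m]][sub$group == g1]
      v2 <- sub[[m]][sub$group == g2]
      tibble(
        roi = r, measure = m,
        mean_1 = mean(v1, na.rm = TRUE), sd_1 = sd(v1, na.rm = TRUE),
        mean_2 = mean(v2, na.rm = TRUE), sd_2 = sd(v2, na.rm = TRUE),
        p_uncorrected = rank_sum_test(v1, v2)
      )
    })
  })
  names(rows)[names(rows) == "mean_1"] <- paste0("mean_", g1)
  names(rows)[names(rows) == "sd_1"] <- paste0("sd_", g1)
  names(rows)[names(rows) == "mean_2"] <- paste0("mean_", g2)
  names(rows)[names(rows) == "sd_2"] <- paste0("sd_", g2)

  fam <- rows$measure %in% corrected_measures
  m_comp <- sum(fam)
  corr <- if (m_comp > 0) bonferroni(alpha, m_comp) else
    list(corrected_threshold = alpha, display_threshold = round(alpha, 3))
  rows$in_family <- fam
  rows$significant_after_bonferroni <- fam & rows$p_uncorrected < corr$corrected_threshold

  structure(
    list(table = rows, alpha = alpha, n_comparisons = m_comp,
         corrected_threshold = corr$corrected_threshold,
         display_threshold = corr$display_threshold,
         groups = c(g1, g2)),
    class = "natsc_group_comparison"
  )
}

#' @export
print.natsc_group_comparison <- function(x, ...) {
  cat("<natsc_group_comparison> ", x$groups[1], " vs ", x$groups[2],
      "; Bonferroni over ", x$n_comparisons, " comparisons, threshold ",
      format(x$display_threshold), "\n", sep = "")
  print(x$table, n = nrow(x$table))
  invisible(x)
}
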
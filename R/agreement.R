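# Agreement battery comparing directly derived and prorated SWLS scores.
# Sign convention throughout: difference = direct - prorated, so a negative
# mean difference means the prorated score runs higher on average.

check_paired <- function(direct, prorated, min_n = 2L, range = TRUE) {
  if (length(direct) != length(prorated)) {
    stop("direct and prorated vectors must be index-aligned and equal length",
         call. = FALSE)
  }
  if (anyNA(direct) || anyNA(prorated)) {
    stop("paired scores must be complete (no missing entries)", call. = FALSE)
  }
  if (length(direct) < min_n) {
    stop("need at least ", min_n, " paired scores", call. = FALSE)
  }
  if (range &&
      (any(direct < 5 | direct > 35) || any(prorated < 5 | prorated > 35))) {
    stop("scores outside the 5-35 metric", call. = FALSE)
  }
  invisible(length(direct))
}

#' Difference statistics for paired direct and prorated scores
#'
#' Means and sample (n-1) standard deviations of the signed differences
#' `direct - prorated` and of their absolute values.
#'
#' @param direct,prorated Equal-length numeric vectors of scores on the
#'   5-item metric, aligned by respondent; n >= 2.
#' @return A list with `n`, `mean_diff`, `sd_diff`, `mean_abs_diff`,
#'   `sd_abs_diff`.
#' @examples
#' difference_stats(c(20, 22, 25), c(21.25, 22.5, 23.75))
#' @export
difference_stats <- function(direct, prorated) {
  n <- check_paired(direct, prorated)
  d <- direct - prorated
  out <- list(
    n = n,
    mean_diff = mean(d),
    sd_diff = stats::sd(d),
    mean_abs_diff = mean(abs(d)),
    sd_abs_diff = stats::sd(abs(d))
  )
  class(out) <- "swls_diff_stats"
  out
}

#' Bland-Altman 95% limits of agreement
#'
#' `mean_diff +/- 1.96 * sd_diff`; under approximate normality the interval
#' is expected to contain about 95% of individual differences. Computed on
#' exact (unrounded) statistics.
#'
#' @param diff_stats Output of [difference_stats()], or any list with
#'   `mean_diff` and `sd_diff`.
#' @return A list with `lower`, `upper`, `mean_diff`, `sd_diff`.
#' @export
limits_of_agreement <- function(diff_stats) {
  m <- diff_stats$mean_diff
  s <- diff_stats$sd_diff
  if (is.null(m) || is.null(s) || is.na(m) || is.na(s) || s < 0) {
    stop("need valid mean_diff and nonnegative sd_diff", call. = FALSE)
  }
  list(lower = m - 1.96 * s, upper = m + 1.96 * s, mean_diff = m, sd_diff = s)
}

#' Pearson correlation between direct and prorated scores
#'
#' Product-moment correlation, with the conventional qualitative flag
#' "very high positive" when r > 0.9. A constant vector leaves the
#' correlation undefined; it is reported as `NA` (never silently 0).
#'
#' @inheritParams difference_stats
#' @return A list with `r`, `very_high` (logical, `NA` when r undefined)
#'   and `n`.
#' @export
pearson_r <- function(direct, prorated) {
  n <- check_paired(direct, prorated, min_n = 3L)
  if (stats::sd(direct) == 0 || stats::sd(prorated) == 0) {
    warning("correlation undefined: constant score vector", call. = FALSE)
    return(list(r = NA_real_, very_high = NA, n = n))
  }
  r <- stats::cor(direct, prorated)
  list(r = r, very_high = r > 0.9, n = n)
}

#' Two-way crossed ANOVA decomposition for paired measurements
#'
#' Decomposes an n-subjects-by-2-measures complete layout (no replication)
#' into between-subjects, between-measures, and residual sums of squares;
#' the three components sum to the total. These mean squares underlie both
#' ICC variants.
#'
#' @inheritParams difference_stats
#' @return A list with mean squares `msr` (subjects), `msc` (measures),
#'   `mse` (residual), their `ss_*` and `df_*` counterparts, `n`, and `k = 2`.
#' @examples
#' anova_two_way(c(1, 3, 5, 7), c(2, 4, 6, 8))
#' @export
anova_two_way <- function(direct, prorated) {
  n <- check_paired(direct, prorated, range = FALSE)
  x <- cbind(direct, prorated)
  k <- 2L
  g <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ss_rows <- k * sum((row_m - g)^2)
  ss_cols <- n * sum((col_m - g)^2)
  ss_total <- sum((x - g)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  df_rows <- n - 1L
  df_cols <- k - 1L
  df_err <- (n - 1L) * (k - 1L)
  list(
    msr = ss_rows / df_rows, msc = ss_cols / df_cols, mse = ss_err / df_err,
    ss_rows = ss_rows, ss_cols = ss_cols, ss_err = ss_err, ss_total = ss_total,
    df_rows = df_rows, df_cols = df_cols, df_err = df_err,
    n = n, k = k
  )
}

#' Threshold proportions of absolute score differences
#'
#' For each threshold t, the fraction of respondents whose absolute
#' difference is strictly below t. The published benchmarks use t = 2, 3,
#' and 4 points (4 points is roughly half a standard deviation of SWLS
#' totals in traumatic-injury samples).
#'
#' @param diffs Numeric vector of signed or absolute differences.
#' @param thresholds Numeric thresholds; default `c(2, 3, 4)`.
#' @return Named numeric vector of proportions, one per threshold.
#' @examples
#' threshold_proportions(c(0, 1, 2, 3, 4))
#' @export
threshold_proportions <- function(diffs, thresholds = c(2, 3, 4)) {
  if (length(diffs) == 0L) stop("empty input", call. = FALSE)
  if (anyNA(diffs)) stop("missing differences", call. = FALSE)
  out <- vapply(thresholds, function(t) mean(abs(diffs) < t), numeric(1))
  names(out) <- paste0("lt_", thresholds)
  out
}

#' Category concordance between two classifications
#'
#' Cross-classifies respondents by the satisfaction category of each score
#' and summarises how many stay in the same band, drop to a lower one, or
#' rise to a higher one under the prorated score.
#'
#' @param direct_cats,prorated_cats Equal-length category vectors as
#'   returned by [classify_swls()] (ordered factors on the six bands).
#' @return A list with `prop_same`, `prop_lower`, `prop_higher` (prorated
#'   below/above direct), `max_abs_shift` (largest rank change), and
#'   `crosstab` (6 x 6 count table, direct in rows).
#' @export
category_concordance <- function(direct_cats, prorated_cats) {
  if (length(direct_cats) != length(prorated_cats)) {
    stop("category vectors must be equal length", call. = FALSE)
  }
  if (length(direct_cats) == 0L) stop("empty input", call. = FALSE)
  lv <- swls_category_labels()
  dc <- factor(as.character(direct_cats), levels = lv, ordered = TRUE)
  pc <- factor(as.character(prorated_cats), levels = lv, ordered = TRUE)
  if (anyNA(dc) || anyNA(pc)) {
    stop("unrecognised category label", call. = FALSE)
  }
  shift <- as.integer(pc) - as.integer(dc)
  list(
    prop_same = mean(shift == 0L),
    prop_lower = mean(shift < 0L),
    prop_higher = mean(shift > 0L),
    max_abs_shift = max(abs(shift)),
    crosstab = table(direct = dc, prorated = pc)
  )
}

#' Full agreement report for one sample of paired scores
#'
#' Assembles the complete validation battery for a direct-vs-prorated
#' comparison: sample moments of the 4-item sum and of both scores,
#' difference statistics, Bland-Altman limits, Pearson correlation, both
#' single-measure ICC variants with 95% confidence intervals, threshold
#' proportions, and category concordance. One such report corresponds to
#' one row of a published agreement table.
#'
#' @inheritParams difference_stats
#' @param label Group label carried into the report (default "overall").
#' @param alpha Two-sided type-I error for the ICC confidence intervals.
#' @return An object of class `swls_agreement`; see
#'   [as.data.frame.swls_agreement()] for the one-row tabular form.
#' @export
agreement_report <- function(direct, prorated, label = "overall",
                             alpha = 0.05) {
  n <- check_paired(direct, prorated)
  sum4 <- prorated / 1.25
  ds <- difference_stats(direct, prorated)
  out <- list(
    label = label,
    n = n,
    sum4_mean = mean(sum4), sum4_sd = stats::sd(sum4),
    direct_mean = mean(direct), direct_sd = stats::sd(direct),
    prorated_mean = mean(prorated), prorated_sd = stats::sd(prorated),
    diff = ds,
    loa = limits_of_agreement(ds),
    pearson = pearson_r(direct, prorated),
    icc = icc_pair(direct, prorated, alpha = alpha),
    thresholds = threshold_proportions(direct - prorated),
    concordance = category_concordance(classify_swls(direct),
                                       classify_swls(prorated))
  )
  class(out) <- "swls_agreement"
  out
}

#' @export
print.swls_agreement <- function(x, ...) {
  cat("SWLS direct vs prorated agreement -- ", x$label,
      " (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  4-item sum    %.1f (SD %.1f)\n", x$sum4_mean, x$sum4_sd))
  cat(sprintf("  direct score  %.1f (SD %.1f)\n", x$direct_mean, x$direct_sd))
  cat(sprintf("  prorated      %.1f (SD %.1f)\n", x$prorated_mean,
              x$prorated_sd))
  cat(sprintf("  difference    %.2f (SD %.2f); |diff| %.2f (SD %.2f)\n",
              x$diff$mean_diff, x$diff$sd_diff, x$diff$mean_abs_diff,
              x$diff$sd_abs_diff))
  cat(sprintf("  95%% limits of agreement  %.1f to %.1f\n",
              x$loa$lower, x$loa$upper))
  cat(sprintf("  Pearson r  %.2f%s\n", x$pearson$r,
              if (isTRUE(x$pearson$very_high)) "  (very high)" else ""))
  print(x$icc)
  tp <- x$thresholds
  cat(sprintf("  |diff| < 2: %.0f%%   < 3: %.0f%%   < 4: %.0f%%\n",
              100 * tp[["lt_2"]], 100 * tp[["lt_3"]], 100 * tp[["lt_4"]]))
  cc <- x$concordance
  cat(sprintf(
    "  category: %.0f%% same, %.0f%% lower, %.0f%% higher (max shift %d)\n",
    100 * cc$prop_same, 100 * cc$prop_lower, 100 * cc$prop_higher,
    cc$max_abs_shift))
  invisible(x)
}

#' One-row tabular form of an agreement report
#'
#' Mirrors the layout of a published agreement table: group, n, mean (SD)
#' of the 4-item sum, direct and prorated scores, the signed and absolute
#' differences, r, and the headline absolute-agreement ICC with its CI.
#' All values are exact; round only for display.
#'
#' @param x An `swls_agreement` object.
#' @param row.names,optional,... Ignored; present for the generic.
#' @export
as.data.frame.swls_agreement <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  data.frame(
    group = x$label, n = x$n,
    sum4_mean = x$sum4_mean, sum4_sd = x$sum4_sd,
    direct_mean = x$direct_mean, direct_sd = x$direct_sd,
    prorated_mean = x$prorated_mean, prorated_sd = x$prorated_sd,
    diff_mean = x$diff$mean_diff, diff_sd = x$diff$sd_diff,
    abs_diff_mean = x$diff$mean_abs_diff, abs_diff_sd = x$diff$sd_abs_diff,
    loa_lower = x$loa$lower, loa_upper = x$loa$upper,
    pearson_r = x$pearson$r,
    icc_agreement = x$icc$agreement$estimate,
    icc_agreement_lower = x$icc$agreement$ci95[1],
    icc_agreement_upper = x$icc$agreement$ci95[2],
    icc_consistency = x$icc$consistency$estimate,
    prop_lt_2 = x$thresholds[["lt_2"]],
    prop_lt_3 = x$thresholds[["lt_3"]],
    prop_lt_4 = x$thresholds[["lt_4"]],
    prop_same_category = x$concordance$prop_same,
    prop_lower_category = x$concordance$prop_lower,
    prop_higher_category = x$concordance$prop_higher,
    stringsAsFactors = FALSE
  )
}
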
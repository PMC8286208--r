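# Single-measure intraclass correlation coefficients from the two-way
# crossed ANOVA, in both the consistency (C,1) and absolute-agreement (A,1)
# definitions. The agreement form penalises a systematic offset between the
# two measures; the consistency form does not. Reports in this literature
# often label the two-way mixed single-measure ICC "(3,1)" while describing
# absolute agreement, so both variants are always computed and labelled.

icc_interpretation <- function(est) {
  if (is.na(est)) return(NA_character_)
  if (est < 0.5) "poor"
  else if (est <= 0.75) "moderate"
  else if (est <= 0.9) "good"
  else "excellent"
}

# Exact F-based CI for the consistency form (two-way mixed, single measure).
icc_consistency_ci <- function(ms, alpha) {
  n <- ms$n; k <- ms$k
  if (ms$mse == 0) {
    # perfect fit: estimate is 1 (or undefined); interval degenerates
    return(c(1, 1))
  }
  fobs <- ms$msr / ms$mse
  fl <- fobs / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
  fu <- fobs * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
  c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
}

# Satterthwaite-approximation CI for the absolute-agreement form
# (McGraw & Wong), using the point estimate in the df weights.
icc_agreement_ci <- function(ms, est, alpha) {
  n <- ms$n; k <- ms$k
  msr <- ms$msr; msc <- ms$msc; mse <- ms$mse
  if (is.na(est)) return(c(NA_real_, NA_real_))
  if (est >= 1 || (mse == 0 && msc == 0)) return(c(1, 1))
  a <- (k * est) / (n * (1 - est))
  b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fl <- stats::qf(1 - alpha / 2, n - 1, v)
  fu <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  c(lower, upper)
}

#' Intraclass correlation between direct and prorated scores
#'
#' Computes both single-measure ICC variants from the two-way crossed
#' ANOVA of an n-subjects-by-2-measures layout:
#' \describe{
#'   \item{consistency (C,1)}{`(MSR - MSE) / (MSR + (k-1) MSE)` -- blind to
#'     a constant offset between the measures.}
#'   \item{absolute agreement (A,1)}{`(MSR - MSE) / (MSR + (k-1) MSE +
#'     (k/n)(MSC - MSE))` -- an offset between the measures lowers it.}
#' }
#' 95% confidence intervals use exact F bounds for the consistency form and
#' the Satterthwaite-degrees-of-freedom approximation for the agreement
#' form. Each estimate carries the conventional qualitative band: poor
#' (< 0.5), moderate (0.5--0.75), good (0.75--0.9), excellent (> 0.9).
#' The headline variant is absolute agreement; the consistency variant is
#' always reported alongside because the field's "(3,1)" label is
#' ambiguous between the two.
#'
#' @inheritParams difference_stats
#' @param alpha Two-sided type-I error for the confidence intervals.
#' @return An object of class `swls_icc`: a list with elements `agreement`
#'   and `consistency`, each holding `estimate`, `variant`, `ci95`, and
#'   `interpretation`, plus the underlying `anova` decomposition. When all
#'   mean squares are zero the estimates are undefined and reported as `NA`.
#' @examples
#' icc_pair(c(1, 3, 5, 7), c(2, 4, 6, 8))
#' @export
icc_pair <- function(direct, prorated, alpha = 0.05) {
  ms <- anova_two_way(direct, prorated)
  k <- ms$k; n <- ms$n
  denom_c <- ms$msr + (k - 1) * ms$mse
  denom_a <- denom_c + (k / n) * (ms$msc - ms$mse)
  est_c <- if (denom_c == 0) NA_real_ else (ms$msr - ms$mse) / denom_c
  est_a <- if (denom_a == 0) NA_real_ else (ms$msr - ms$mse) / denom_a
  out <- list(
    agreement = list(
      estimate = est_a,
      variant = "absolute agreement, single measure (A,1)",
      ci95 = if (is.na(est_a)) c(NA_real_, NA_real_)
             else icc_agreement_ci(ms, est_a, alpha),
      interpretation = icc_interpretation(est_a)
    ),
    consistency = list(
      estimate = est_c,
      variant = "consistency, single measure (C,1)",
      ci95 = if (is.na(est_c)) c(NA_real_, NA_real_)
             else icc_consistency_ci(ms, alpha),
      interpretation = icc_interpretation(est_c)
    ),
    anova = ms,
    alpha = alpha
  )
  class(out) <- "swls_icc"
  out
}

#' @export
print.swls_icc <- function(x, ...) {
  fmt <- function(v) {
    if (is.na(v$estimate)) {
      sprintf("  ICC %-42s undefined", v$variant)
    } else {
      sprintf("  ICC %-42s %.2f (95%% CI %.2f-%.2f), %s",
              v$variant, v$estimate, v$ci95[1], v$ci95[2], v$interpretation)
    }
  }
  cat(fmt(x$agreement), "\n", fmt(x$consistency), "\n", sep = "")
  invisible(x)
}
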
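# Shared fixtures and independent oracles for the test suite.

# Random paired scores on the 5-35 metric (direct integer, prorated on the
# quarter-point grid), built from simulated item responses so every pair is
# attainable.
random_paired <- function(n, seed) {
  set.seed(seed)
  items <- matrix(sample(1:7, n * 5, replace = TRUE), ncol = 5)
  sum4 <- rowSums(items[, 1:4])
  list(direct = sum4 + items[, 5], prorated = 1.25 * sum4, items = items)
}

# Independent ANOVA route: mean squares from anova(lm()) on the long
# layout, not from the package's closed-form decomposition.
anova_oracle <- function(y1, y2) {
  n <- length(y1)
  long <- data.frame(
    y = c(y1, y2),
    subj = factor(rep(seq_len(n), 2)),
    meas = factor(rep(1:2, each = n))
  )
  tab <- anova(stats::lm(y ~ subj + meas, data = long))
  list(msr = tab["subj", "Mean Sq"], msc = tab["meas", "Mean Sq"],
       mse = tab["Residuals", "Mean Sq"], n = n, k = 2)
}

# ICC definitions applied to oracle mean squares (variance-components
# brute force, written out independently of icc_pair()).
icc_oracle <- function(y1, y2) {
  ms <- anova_oracle(y1, y2)
  k <- ms$k
  cons <- (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse)
  agre <- (ms$msr - ms$mse) /
    (ms$msr + (k - 1) * ms$mse + (k / ms$n) * (ms$msc - ms$mse))
  list(consistency = cons, agreement = agre)
}

# 30 paired scores frozen from an external reference run: a third-party
# two-way ICC implementation (pingouin.intraclass_corr) reported
# ICC(A,1) = 0.9262565601, ICC(C,1) = 0.9275111063, both CIs [0.85, 0.96]
# at its printed 2-decimal precision.
icc_reference_fixture <- function() {
  list(
    direct = c(25, 13, 24, 24, 9, 14, 21, 17, 19, 16, 26, 25, 19, 27, 23,
               15, 24, 15, 26, 20, 19, 17, 25, 19, 17, 17, 23, 24, 21, 24),
    prorated = c(20, 14, 26, 27, 10, 14, 21, 18, 22, 15, 24, 24, 20, 28, 24,
                 17, 22, 15, 27, 20, 20, 16, 28, 19, 16, 19, 23, 23, 24, 24),
    icc_a1 = 0.9262565601,
    icc_c1 = 0.9275111063,
    ci_2dp = c(0.85, 0.96)
  )
}

# Published overall-sample anchors used across tests: item-level means of
# the five SWLS items in the pooled traumatic-injury sample.
published_item_means <- c(3.76, 3.80, 4.32, 4.53, 3.72)
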
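test_that("difference statistics follow the direct-minus-prorated convention with sample SD", {
  ds <- difference_stats(c(20, 22, 25), c(20, 22, 25))
  expect_equal(ds$mean_diff, 0)
  expect_equal(ds$sd_diff, 0)
  expect_equal(ds$mean_abs_diff, 0)

  # diffs +1 and -1: mean 0, sample variance 2
  ds <- difference_stats(c(21, 19), c(20, 20))
  expect_equal(ds$mean_diff, 0)
  expect_equal(ds$sd_diff, sqrt(2), tolerance = 1e-12)
  expect_equal(ds$mean_abs_diff, 1)

  expect_error(difference_stats(c(20, 21), c(20, 21, 22)), "equal length")
  expect_error(difference_stats(20, 21), "at least 2")
  expect_gte(ds$mean_abs_diff, abs(ds$mean_diff))
})

test_that("limits of agreement are mean difference plus or minus 1.96 SD", {
  loa <- limits_of_agreement(list(mean_diff = 0, sd_diff = 1))
  expect_equal(c(loa$lower, loa$upper), c(-1.96, 1.96))
  loa <- limits_of_agreement(list(mean_diff = -0.39, sd_diff = 1.95))
  expect_equal(c(loa$lower, loa$upper), c(-4.212, 3.432), tolerance = 1e-12)
  expect_equal(loa$upper - loa$lower, 2 * 1.96 * 1.95, tolerance = 1e-12)
  loa <- limits_of_agreement(list(mean_diff = -0.5, sd_diff = 0))
  expect_equal(c(loa$lower, loa$upper), c(-0.5, -0.5))
})

test_that("limits of agreement cover ~95% of normal differences", {
  set.seed(101)
  d <- rnorm(10000, mean = -0.4, sd = 2)
  m <- mean(d); s <- sd(d)
  loa <- limits_of_agreement(list(mean_diff = m, sd_diff = s))
  coverage <- mean(d >= loa$lower & d <= loa$upper)
  expect_lt(abs(coverage - 0.95), 0.01)
})

test_that("pearson correlation matches a hand product-moment oracle and flags very high values", {
  p <- random_paired(50, seed = 21)
  got <- pearson_r(p$direct, p$prorated)
  # independent oracle: explicit product-moment formula
  x <- p$direct; y <- p$prorated
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$r, r_hand, tolerance = 1e-12)

  expect_equal(pearson_r(c(5, 10, 15), c(5, 10, 15))$r, 1)
  expect_equal(pearson_r(c(5, 10, 15), c(35, 30, 25))$r, -1)
  expect_equal(pearson_r(c(5, 10, 15), c(6, 9, 16))$r, 0.9743547037,
               tolerance = 1e-9)
  expect_true(pearson_r(c(5, 10, 15), c(6, 9, 16))$very_high)

  expect_warning(res <- pearson_r(c(5, 10, 15), c(20, 20, 20)), "constant")
  expect_true(is.na(res$r))
})

test_that("pearson correlation is invariant under positive affine transforms", {
  p <- random_paired(40, seed = 22)
  base <- pearson_r(p$direct, p$prorated)$r
  x <- 2 * p$direct - 3
  y <- 0.5 * p$prorated + 7
  r2 <- suppressWarnings(stats::cor(x, y))
  expect_equal(base, r2, tolerance = 1e-12)
})

test_that("two-way ANOVA decomposition matches the worked example and conserves sums of squares", {
  ms <- anova_two_way(c(1, 3, 5, 7), c(2, 4, 6, 8))
  expect_equal(ms$msr, 40 / 3, tolerance = 1e-12)
  expect_equal(ms$msc, 2, tolerance = 1e-12)
  expect_equal(ms$mse, 0, tolerance = 1e-12)
  expect_equal(ms$ss_total, 42, tolerance = 1e-12)

  # identical columns: only subject variance
  ms <- anova_two_way(c(6, 10, 20), c(6, 10, 20))
  expect_equal(ms$msc, 0)
  expect_equal(ms$mse, 0)
  expect_gt(ms$msr, 0)

  # all entries equal: nothing to decompose
  ms <- anova_two_way(rep(20, 4), rep(20, 4))
  expect_equal(c(ms$msr, ms$msc, ms$mse), c(0, 0, 0))

  set.seed(23)
  for (i in 1:20) {
    n <- sample(2:30, 1)
    y1 <- rnorm(n); y2 <- rnorm(n)
    ms <- anova_two_way(y1, y2)
    expect_equal(ms$ss_rows + ms$ss_cols + ms$ss_err, ms$ss_total,
                 tolerance = 1e-9)
    orc <- anova_oracle(y1, y2)
    expect_equal(ms$msr, orc$msr, tolerance = 1e-9)
    expect_equal(ms$msc, orc$msc, tolerance = 1e-9)
    expect_equal(ms$mse, orc$mse, tolerance = 1e-9)
  }
})

test_that("threshold proportions count strict absolute differences and are monotone", {
  expect_equal(unname(threshold_proportions(rep(0, 5))), c(1, 1, 1))
  expect_equal(unname(threshold_proportions(c(0, 1, 2, 3, 4))),
               c(0.4, 0.6, 0.8))
  expect_equal(unname(threshold_proportions(c(4, -5, 6, 4.5))), c(0, 0, 0))
  expect_error(threshold_proportions(numeric(0)), "empty")

  set.seed(24)
  for (i in 1:10) {
    d <- rnorm(100, sd = 3)
    tp <- threshold_proportions(d)
    expect_true(all(diff(tp) >= 0))
    # sign of each difference is irrelevant
    flip <- d * sample(c(-1, 1), 100, replace = TRUE)
    expect_identical(threshold_proportions(flip), tp)
  }
})

test_that("category concordance counts same, lower, and higher classifications", {
  lv <- swls_category_labels()
  same <- classify_swls(c(6, 12, 22, 33))
  cc <- category_concordance(same, same)
  expect_equal(cc$prop_same, 1)
  expect_equal(cc$max_abs_shift, 0)
  expect_equal(sum(cc$crosstab), 4)

  # 10 pairs: 7 unchanged, 1 down one band, 2 up one band
  direct <- factor(lv[c(3, 3, 3, 3, 3, 3, 3, 3, 3, 3)], levels = lv,
                   ordered = TRUE)
  prorated <- factor(lv[c(3, 3, 3, 3, 3, 3, 3, 2, 4, 4)], levels = lv,
                     ordered = TRUE)
  cc <- category_concordance(direct, prorated)
  expect_equal(cc$prop_same, 0.7)
  expect_equal(cc$prop_lower, 0.1)
  expect_equal(cc$prop_higher, 0.2)
  expect_equal(cc$max_abs_shift, 1)
  expect_equal(cc$prop_same + cc$prop_lower + cc$prop_higher, 1)

  # systematic one-band upshift
  up <- factor(lv[c(2, 3, 4)], levels = lv, ordered = TRUE)
  base <- factor(lv[c(1, 2, 3)], levels = lv, ordered = TRUE)
  expect_equal(category_concordance(base, up)$prop_higher, 1)
  expect_error(category_concordance(base, up[1:2]), "equal length")
})

test_that("agreement report assembles a coherent table row", {
  p <- random_paired(500, seed = 25)
  rep <- agreement_report(p$direct, p$prorated, label = "synthetic")
  df <- as.data.frame(rep)
  expect_identical(nrow(df), 1L)
  expect_equal(df$n, 500)
  expect_equal(df$diff_mean, mean(p$direct - p$prorated), tolerance = 1e-12)
  expect_equal(df$loa_upper - df$loa_lower, 2 * 1.96 * df$diff_sd,
               tolerance = 1e-9)
  expect_equal(df$prop_same_category + df$prop_lower_category +
                 df$prop_higher_category, 1, tolerance = 1e-12)
  expect_equal(df$sum4_mean, mean(p$prorated) / 1.25, tolerance = 1e-12)
  expect_output(print(rep), "limits of agreement")
})
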
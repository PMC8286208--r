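#' Bland-Altman plot for direct vs prorated scores
#'
#' Scatter of the per-respondent difference (direct - prorated) against
#' the pair mean, with a dotted line at the mean difference and dashed
#' lines at the 95% limits of agreement. Scores sit on a quarter-point
#' grid, so heavy overplotting is expected at large n; optional jitter
#' (off by default) separates coincident points without changing any
#' statistic.
#'
#' @inheritParams difference_stats
#' @param title Plot title.
#' @param jitter If `TRUE`, add small positional jitter for display only.
#' @return A ggplot object.
#' @importFrom ggplot2 .data
#' @export
bland_altman_plot <- function(direct, prorated, title = "Bland-Altman plot",
                              jitter = FALSE) {
  check_paired(direct, prorated)
  ds <- difference_stats(direct, prorated)
  loa <- limits_of_agreement(ds)
  df <- data.frame(avg = (direct + prorated) / 2, diff = direct - prorated)
  geom_pts <- if (jitter) {
    ggplot2::geom_jitter(width = 0.15, height = 0.15, alpha = 0.3, size = 0.8)
  } else {
    ggplot2::geom_point(alpha = 0.3, size = 0.8)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$avg, y = .data$diff)) +
    geom_pts +
    ggplot2::geom_hline(yintercept = ds$mean_diff, linetype = "dotted") +
    ggplot2::geom_hline(yintercept = c(loa$lower, loa$upper),
                        linetype = "dashed") +
    ggplot2::labs(
      x = "Mean of direct and prorated score",
      y = "Direct - prorated score",
      title = title,
      subtitle = sprintf("mean difference %.2f; 95%% limits %.1f to %.1f",
                         ds$mean_diff, loa$lower, loa$upper)
    ) +
    ggplot2::theme_minimal()
}
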
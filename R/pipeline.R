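# End-to-end pipeline: wide item CSV in, agreement report(s) and
# Bland-Altman plot out. Computation is always on exact scores; rounding
# happens only when a report is formatted for display.

.item_cols4 <- paste0("item", 1:4)
.item_cols5 <- paste0("item", 1:5)

#' Read a wide-format SWLS item response CSV
#'
#' Expects a header with columns `item1,item2,item3,item4` and optionally
#' `item5`, one respondent per row, responses coded 1--7. Additional
#' columns (e.g. a group identifier) are carried through untouched. Rows
#' failing validation (missing, non-integer, or out-of-range responses) are
#' an error by default: complete-case analyses are biased by silent drops,
#' so dropping must be requested explicitly.
#'
#' @param path CSV file path.
#' @param skip_invalid If `TRUE`, drop malformed rows with a warning that
#'   lists them; if `FALSE` (default), any malformed row is an error.
#' @return A data frame of validated integer item responses plus any extra
#'   columns.
#' @export
read_swls_csv <- function(path, skip_invalid = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_swls_table(df, skip_invalid = skip_invalid)
}

#' Validate a wide item-response table
#'
#' @param df Data frame with columns `item1`..`item4` and optionally
#'   `item5`.
#' @inheritParams read_swls_csv
#' @return The validated data frame (possibly with rows dropped when
#'   `skip_invalid = TRUE`).
#' @export
validate_swls_table <- function(df, skip_invalid = FALSE) {
  if (!all(.item_cols4 %in% names(df))) {
    stop("input must contain columns ", paste(.item_cols4, collapse = ", "),
         call. = FALSE)
  }
  cols <- if ("item5" %in% names(df)) .item_cols5 else .item_cols4
  items <- df[cols]
  ok_cell <- vapply(items, function(v) {
    suppressWarnings(vn <- as.numeric(v))
    !is.na(vn) & vn == round(vn) & vn >= 1 & vn <= 7
  }, logical(nrow(df)))
  ok_cell <- matrix(ok_cell, nrow = nrow(df))
  bad_rows <- which(!apply(ok_cell, 1L, all))
  if (length(bad_rows)) {
    msg <- paste0(length(bad_rows), " malformed row(s) (first few: ",
                  paste(utils::head(bad_rows, 5L), collapse = ", "),
                  "): responses must be integers in [1, 7] with no gaps")
    if (!skip_invalid) stop(msg, call. = FALSE)
    warning(msg, "; dropped", call. = FALSE)
    df <- df[-bad_rows, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no valid rows", call. = FALSE)
  for (cl in cols) df[[cl]] <- as.integer(df[[cl]])
  rownames(df) <- NULL
  df
}

#' Score a table of SWLS responses
#'
#' Appends the 4-item sum, the prorated 5-item score, the directly derived
#' 5-item score (when `item5` is present), and the satisfaction category of
#' each score.
#'
#' @param df A validated response table (see [validate_swls_table()]).
#' @return The input with columns `sum4`, `direct` (if item5 present),
#'   `prorated`, `category_direct` (if item5 present), `category_prorated`
#'   appended.
#' @export
score_table <- function(df) {
  df <- validate_swls_table(df)
  df$sum4 <- df$item1 + df$item2 + df$item3 + df$item4
  if ("item5" %in% names(df)) df$direct <- df$sum4 + df$item5
  df$prorated <- 1.25 * df$sum4
  if ("item5" %in% names(df)) df$category_direct <- classify_swls(df$direct)
  df$category_prorated <- classify_swls(df$prorated)
  df
}

#' Run the full linking validation report
#'
#' Scores every respondent both ways (direct 5-item sum and prorated
#' 4-item estimate) and computes the complete agreement battery for the
#' overall sample and, if a grouping column is given, for each group.
#' Validation requires `item5`: without it there is no direct score to
#' agree with.
#'
#' @param df A response table with complete `item1`..`item5` (and
#'   optionally a grouping column).
#' @param group Optional name of a grouping column (e.g. injury type).
#'   Every distinct value becomes its own group; nothing is dropped.
#' @param alpha Type-I error for ICC confidence intervals.
#' @return An object of class `swls_report`: a list of `swls_agreement`
#'   objects, the overall sample first.
#' @export
run_linking_report <- function(df, group = NULL, alpha = 0.05) {
  df <- validate_swls_table(df)
  if (!"item5" %in% names(df)) {
    stop("validation needs item5: no direct score without it", call. = FALSE)
  }
  scored <- score_table(df)
  reports <- list(
    overall = agreement_report(scored$direct, scored$prorated,
                               label = "overall", alpha = alpha)
  )
  if (!is.null(group)) {
    if (!group %in% names(scored)) {
      stop("grouping column '", group, "' not found", call. = FALSE)
    }
    for (g in unique(as.character(scored[[group]]))) {
      sub <- scored[as.character(scored[[group]]) == g, ]
      reports[[g]] <- agreement_report(sub$direct, sub$prorated,
                                       label = g, alpha = alpha)
    }
  }
  structure(list(reports = reports, group = group, alpha = alpha),
            class = "swls_report")
}

#' @export
print.swls_report <- function(x, ...) {
  for (r in x$reports) {
    print(r)
    cat("\n")
  }
  invisible(x)
}

#' @describeIn run_linking_report Stack all group reports into one table
#'   (one row per group, overall first), with exact unrounded values.
#' @param x An `swls_report`.
#' @param row.names,optional,... Ignored; present for the generic.
#' @export
as.data.frame.swls_report <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  out <- do.call(rbind, lapply(x$reports, as.data.frame))
  rownames(out) <- NULL
  out
}

report_as_list <- function(x) {
  lapply(x$reports, function(r) {
    list(
      group = r$label, n = r$n,
      sum4 = list(mean = r$sum4_mean, sd = r$sum4_sd),
      direct = list(mean = r$direct_mean, sd = r$direct_sd),
      prorated = list(mean = r$prorated_mean, sd = r$prorated_sd),
      difference = list(mean = r$diff$mean_diff, sd = r$diff$sd_diff),
      abs_difference = list(mean = r$diff$mean_abs_diff,
                            sd = r$diff$sd_abs_diff),
      limits_of_agreement = list(lower = r$loa$lower, upper = r$loa$upper),
      pearson = list(r = r$pearson$r,
                     very_high = isTRUE(r$pearson$very_high)),
      icc = list(
        agreement = list(estimate = r$icc$agreement$estimate,
                         ci95 = r$icc$agreement$ci95,
                         interpretation = r$icc$agreement$interpretation),
        consistency = list(estimate = r$icc$consistency$estimate,
                           ci95 = r$icc$consistency$ci95,
                           interpretation = r$icc$consistency$interpretation),
        headline_variant = "absolute agreement (A,1)"
      ),
      threshold_proportions = as.list(r$thresholds),
      concordance = list(
        prop_same = r$concordance$prop_same,
        prop_lower = r$concordance$prop_lower,
        prop_higher = r$concordance$prop_higher,
        max_abs_shift = r$concordance$max_abs_shift,
        crosstab = unclass(as.matrix(unclass(r$concordance$crosstab)))
      )
    )
  })
}

#' Serialise a linking report
#'
#' `write_report_json()` writes the full report (all statistics, both ICC
#' variants, the concordance cross-table) as JSON; re-running an identical
#' configuration on identical input yields a byte-identical file.
#' `write_report_csv()` writes one row per group at display precision:
#' scores to 1 decimal, correlations and ICCs to 2 decimals, proportions
#' to 3; rounding is half-away-from-zero and never feeds back into
#' computation.
#'
#' @param report An `swls_report`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report_as_list(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_report_json
#' @export
write_report_csv <- function(report, path) {
  df <- as.data.frame(report)
  score_cols <- c("sum4_mean", "sum4_sd", "direct_mean", "direct_sd",
                  "prorated_mean", "prorated_sd", "diff_mean", "diff_sd",
                  "abs_diff_mean", "abs_diff_sd", "loa_lower", "loa_upper")
  corr_cols <- c("pearson_r", "icc_agreement", "icc_agreement_lower",
                 "icc_agreement_upper", "icc_consistency")
  prop_cols <- c("prop_lt_2", "prop_lt_3", "prop_lt_4",
                 "prop_same_category", "prop_lower_category",
                 "prop_higher_category")
  df[score_cols] <- lapply(df[score_cols], round_half_up, digits = 1)
  df[corr_cols] <- lapply(df[corr_cols], round_half_up, digits = 2)
  df[prop_cols] <- lapply(df[prop_cols], round_half_up, digits = 3)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Packaged worked examples of the proration technique
#'
#' The standard worked examples for documentation and smoke tests: the
#' all-maximum and all-minimum individual response patterns (prorated to
#' the scale endpoints 35 and 5) and the group-level example built from
#' the published overall item means 3.76, 3.80, 4.32, 4.53, whose 4-item
#' group mean of 16.41 prorates to 20.5125 (20.5 at one decimal).
#'
#' @return A list with `individual` (input vectors and expected prorated
#'   scores) and `group` (item means, expected prorated group mean).
#' @export
worked_example_fixtures <- function() {
  list(
    individual = list(
      maximum = list(items = c(7L, 7L, 7L, 7L), prorated = 35),
      minimum = list(items = c(1L, 1L, 1L, 1L), prorated = 5)
    ),
    group = list(
      item_means = c(3.76, 3.80, 4.32, 4.53),
      sum4_mean = 16.41,
      prorated_mean_exact = 20.5125,
      prorated_mean_1dp = 20.5
    )
  )
}
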
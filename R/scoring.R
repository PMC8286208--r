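#' swlslink: proration-based linking of the 4- and 5-item SWLS
#'
#' The Satisfaction With Life Scale (SWLS) is a 5-item measure of global
#' life satisfaction scored on a 7-point agreement scale; totals run from 5
#' to 35. A modified 4-item form drops the fifth item ("If I could live my
#' life over, I would change almost nothing"), which performs poorly in
#' traumatic-injury populations. This package links the two forms by
#' proration -- the mean of the four retained items is added to their sum --
#' and supplies the agreement battery (Bland-Altman limits, ICC, category
#' concordance) used to validate such a link, plus a synthetic-data
#' generator for correlated Likert items.
#'
#' @keywords internal
"_PACKAGE"

# Likert response bounds shared across the package.
.swls_min_item <- 1L
.swls_max_item <- 7L

#' Validate a set of SWLS item responses
#'
#' Checks that a raw vector is a complete set of 4 or 5 SWLS item responses:
#' every entry an integer on the 7-point agreement scale (1 = strongly
#' disagree ... 7 = strongly agree), no missing values. Out-of-range or
#' non-integer values are rejected, never coerced; proration of incomplete
#' 4-item sets is deliberately unsupported because a 3-of-4 fallback is a
#' different, unvalidated estimator.
#'
#' @param raw A vector of 4 or 5 item responses.
#' @return An integer vector of length 4 or 5.
#' @examples
#' validate_responses(c(7, 7, 7, 7, 7))
#' validate_responses(c(1, 1, 1, 1))
#' @export
validate_responses <- function(raw) {
  if (is.list(raw)) raw <- unlist(raw, use.names = FALSE)
  if (!length(raw) %in% c(4L, 5L)) {
    stop("expected 4 or 5 item responses, got ", length(raw), call. = FALSE)
  }
  if (!is.numeric(raw)) {
    bad <- which(!vapply(raw, function(v) is.numeric(v) && !is.na(v), TRUE))[1]
    stop("non-numeric response at item ", bad, call. = FALSE)
  }
  if (anyNA(raw)) {
    stop("missing response at item ", which(is.na(raw))[1],
         "; proration requires complete items", call. = FALSE)
  }
  not_int <- which(raw != round(raw))
  if (length(not_int)) {
    stop("non-integer response at item ", not_int[1], call. = FALSE)
  }
  oor <- which(raw < .swls_min_item | raw > .swls_max_item)
  if (length(oor)) {
    stop("value out of range [1, 7] at item ", oor[1], call. = FALSE)
  }
  as.integer(raw)
}

#' Directly derived 5-item SWLS total score
#'
#' The ordinary SWLS total: the sum of all five item responses, an integer
#' in 5--35. Higher scores indicate greater life satisfaction.
#'
#' @param items A complete set of 5 item responses (validated on entry).
#' @return Integer total in \[5, 35\].
#' @seealso [prorated_score()] for the linked 4-item estimate.
#' @examples
#' direct_score(c(3, 4, 5, 6, 2)) # 20
#' @export
direct_score <- function(items) {
  items <- validate_responses(items)
  if (length(items) != 5L) {
    stop("direct scoring needs all 5 items; got ", length(items), call. = FALSE)
  }
  sum(items)
}

#' Prorated 5-item score from the first four items
#'
#' Links the 4-item SWLS to the 5-item metric by proration: the missing
#' fifth item is imputed with the mean of the four observed items, so the
#' prorated total is `sum4 + sum4/4 = 1.25 * sum4`. Quarter-point values
#' are exact in double precision, so no rounding occurs here; round only
#' for display. A 5-item record is accepted but its fifth item is ignored,
#' mirroring how a 4-item administration would behave.
#'
#' @param items A complete set of 4 (or 5) item responses.
#' @return Prorated score in \[5, 35\], an exact multiple of 1.25.
#' @examples
#' prorated_score(c(3, 4, 5, 6)) # 22.5
#' prorated_score(c(7, 7, 7, 7)) # 35
#' @export
prorated_score <- function(items) {
  items <- validate_responses(items)
  sum4 <- sum(items[1:4])
  sum4 * 1.25
}

#' Group-level prorated mean on the 5-item metric
#'
#' Proration is linear, so a group's mean prorated score can be computed
#' directly from 4-item sums (or from an already-averaged 4-item group
#' mean): `1.25 * mean(sum4)`. This equals the arithmetic mean of the
#' per-respondent prorated scores exactly.
#'
#' @param sums4 Numeric vector of 4-item sums, or a single 4-item group
#'   mean. Values must lie in \[4, 28\].
#' @return Group mean on the 5-item metric.
#' @examples
#' group_prorated_mean(sum(c(3.76, 3.80, 4.32, 4.53))) # 20.5125
#' @export
group_prorated_mean <- function(sums4) {
  if (length(sums4) == 0L) stop("empty input", call. = FALSE)
  if (anyNA(sums4)) stop("missing values in 4-item sums", call. = FALSE)
  if (any(sums4 < 4 | sums4 > 28)) {
    stop("4-item sums must lie in [4, 28]", call. = FALSE)
  }
  1.25 * mean(sums4)
}

#' Satisfaction category labels, in ascending order
#' @return Character vector of the six band labels.
#' @export
swls_category_labels <- function() {
  c("extremely dissatisfied", "dissatisfied", "slightly dissatisfied",
    "neutral or slightly satisfied", "satisfied", "extremely satisfied")
}

# Lower edges of the six bands. The published integer cutoffs (5-9, 10-14,
# 15-19, 20-25, 26-30, 31-35) leave gaps for fractional prorated scores;
# half-open intervals [5,10), [10,15), [15,20), [20,26), [26,31), [31,35]
# extend them without moving any integer assignment.
.swls_band_edges <- c(5, 10, 15, 20, 26, 31)

#' Classify an SWLS score into a satisfaction category
#'
#' Applies the published interpretive benchmarks: 31--35 extremely
#' satisfied, 26--30 satisfied, 20--25 neutral or slightly satisfied,
#' 15--19 slightly dissatisfied, 10--14 dissatisfied, 5--9 extremely
#' dissatisfied. Fractional prorated scores fall in the half-open
#' extensions of these bands (e.g. 25.5 is still "neutral or slightly
#' satisfied"); every integer score keeps its published band.
#'
#' @param score Numeric vector of scores on the 5-item metric, in \[5, 35\].
#' @return Ordered factor with the six category levels.
#' @examples
#' classify_swls(c(5, 22.5, 35))
#' @export
classify_swls <- function(score) {
  if (length(score) == 0L) stop("empty input", call. = FALSE)
  if (anyNA(score)) stop("missing score", call. = FALSE)
  if (any(score < 5 | score > 35)) {
    stop("score outside [5, 35]: ", score[which(score < 5 | score > 35)[1]],
         call. = FALSE)
  }
  rank <- findInterval(score, .swls_band_edges)
  factor(swls_category_labels()[rank], levels = swls_category_labels(),
         ordered = TRUE)
}

#' Crosswalk table from 4-item sums to the 5-item metric
#'
#' One row per attainable 4-item sum (4 through 28) giving the exact
#' prorated 5-item equivalent, the value rounded to one decimal for
#' reporting, and the satisfaction category. This is the static linking
#' table a clinician can apply without any software.
#'
#' @return A data frame with columns `sum4`, `prorated_exact`,
#'   `prorated_1dp`, `category`.
#' @examples
#' head(crosswalk_table())
#' @export
crosswalk_table <- function() {
  sum4 <- 4:28
  exact <- 1.25 * sum4
  data.frame(
    sum4 = sum4,
    prorated_exact = exact,
    prorated_1dp = round_half_up(exact, 1),
    category = classify_swls(exact)
  )
}

#' Round half away from zero
#'
#' Display rounding for printed score tables: quarter-point prorated values
#' round upward in magnitude at the half (21.25 becomes 21.3), matching the
#' convention of published tables. Base `round()` is half-to-even and would
#' give 21.2. Used only at formatting time, never in computation.
#'
#' @param x Numeric vector.
#' @param digits Decimal places to keep.
#' @return `x` rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
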
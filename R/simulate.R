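# Seedable generator of correlated 7-point Likert responses. A latent
# multivariate normal is discretised by rounding to the nearest integer and
# clipping to [1, 7]; rounding and clipping bias the post-discretisation
# mean away from the latent mean, so latent means are calibrated against
# the exact analytic marginal of the round-and-clip transform.

#' Configuration for the correlated Likert response generator
#'
#' @param n Number of respondents (>= 1).
#' @param target_means Five target item means, each strictly inside (1, 7).
#' @param target_sds Five positive target item SDs. Means are calibrated
#'   hard; SDs are used as the latent scale and only loosely realised,
#'   because round-and-clip compresses variance (the achieved SDs are
#'   reported by [calibrate_latent_means()]).
#' @param rho Inter-item latent correlation: a scalar for an exchangeable
#'   structure, or a full 5 x 5 positive semi-definite correlation matrix.
#' @param seed Integer seed; identical configs give identical matrices.
#' @return An object of class `likert_sim_config`.
#' @seealso [default_swls_profile()] for the SWLS overall-sample profile.
#' @export
likert_sim_config <- function(n, target_means, target_sds, rho = 0.65,
                              seed = 1L) {
  if (length(n) != 1L || is.na(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  if (length(target_means) != 5L || length(target_sds) != 5L) {
    stop("target_means and target_sds must have length 5", call. = FALSE)
  }
  if (any(target_means <= 1 | target_means >= 7)) {
    stop("target means must lie strictly inside (1, 7)", call. = FALSE)
  }
  if (any(target_sds <= 0)) stop("target SDs must be positive", call. = FALSE)
  if (is.matrix(rho)) {
    if (!all(dim(rho) == c(5L, 5L)) || any(abs(diag(rho) - 1) > 1e-12) ||
        any(abs(rho - t(rho)) > 1e-12)) {
      stop("rho matrix must be symmetric 5 x 5 with unit diagonal",
           call. = FALSE)
    }
    R <- rho
  } else {
    if (length(rho) != 1L || rho < -0.25 || rho > 1) {
      stop("scalar rho must give a valid exchangeable correlation",
           call. = FALSE)
    }
    R <- matrix(rho, 5L, 5L)
    diag(R) <- 1
  }
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("correlation matrix is not positive semi-definite", call. = FALSE)
  }
  structure(
    list(n = as.integer(n), target_means = as.numeric(target_means),
         target_sds = as.numeric(target_sds), corr = R,
         seed = as.integer(seed)),
    class = "likert_sim_config"
  )
}

#' @export
print.likert_sim_config <- function(x, ...) {
  cat("Likert simulation config: n =", x$n, ", seed =", x$seed, "\n")
  cat("  target means:", paste(sprintf("%.2f", x$target_means),
                               collapse = " "), "\n")
  cat("  target SDs:  ", paste(sprintf("%.2f", x$target_sds),
                               collapse = " "), "\n")
  off <- x$corr[upper.tri(x$corr)]
  if (length(unique(round(off, 12))) == 1L) {
    cat("  exchangeable latent correlation rho =", off[1], "\n")
  } else {
    cat("  full latent correlation matrix supplied\n")
  }
  invisible(x)
}

#' Default profile emulating the SWLS overall traumatic-injury sample
#'
#' Target item means 3.76, 3.80, 4.32, 4.53, 3.72 and SDs 2.07, 2.04,
#' 2.07, 2.00, 2.18, at n = 17,897 -- the published overall moments of the
#' five SWLS items in a pooled spinal cord injury / traumatic brain injury
#' / burn injury sample. The inter-item latent correlation (0.65,
#' exchangeable) is not a published value: it is a documented assumption
#' chosen to place internal consistency in the high range reported for the
#' scale, and can be overridden.
#'
#' @param n Sample size; default 17897.
#' @param seed Seed; default 20210717.
#' @return A `likert_sim_config`.
#' @export
default_swls_profile <- function(n = 17897L, seed = 20210717L) {
  likert_sim_config(
    n = n,
    target_means = c(3.76, 3.80, 4.32, 4.53, 3.72),
    target_sds = c(2.07, 2.04, 2.07, 2.00, 2.18),
    rho = 0.65,
    seed = seed
  )
}

# Exact first two moments of round(clip(N(mu, sigma))) on the 1..7 grid.
# Category k has probability mass between cutpoints k - 0.5 and k + 0.5
# (open-ended at 1 and 7 because of clipping).
discretised_moments <- function(mu, sigma) {
  cuts <- seq(1.5, 6.5, by = 1)
  cdf <- stats::pnorm(cuts, mean = mu, sd = sigma)
  p <- diff(c(0, cdf, 1))
  k <- 1:7
  m1 <- sum(k * p)
  m2 <- sum(k^2 * p)
  list(p = p, mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}

#' Calibrate latent normal means to hit target item means
#'
#' For each item, solves (by root-finding on the exact analytic marginal of
#' the round-and-clip transform) for the latent normal mean whose
#' discretised 1--7 response has the target mean. Latent SDs are taken as
#' the target SDs; the achieved post-discretisation SDs are reported, not
#' forced. Calibration fails when a target is effectively a boundary point
#' -- when realising it would pile more than 90% of the mass on response 1
#' or 7, as for a target mean of 6.99 with SD 2.5 -- because no interior
#' latent distribution reaches it.
#'
#' @param cfg A `likert_sim_config`.
#' @return An object of class `likert_calibration`: `latent_means`,
#'   `latent_sds`, `achieved_means`, `achieved_sds` (all analytic, so the
#'   calibration is deterministic without Monte Carlo).
#' @export
calibrate_latent_means <- function(cfg) {
  stopifnot(inherits(cfg, "likert_sim_config"))
  latent <- numeric(5L)
  ach_m <- numeric(5L)
  ach_s <- numeric(5L)
  for (j in 1:5) {
    target <- cfg$target_means[j]
    sigma <- cfg$target_sds[j]
    f <- function(mu) discretised_moments(mu, sigma)$mean - target
    sol <- tryCatch(
      stats::uniroot(f, lower = -30, upper = 40, tol = 1e-10),
      error = function(e) NULL
    )
    if (is.null(sol)) {
      stop("calibration failure for item ", j, ": target mean ", target,
           " unreachable with SD ", sigma, call. = FALSE)
    }
    mom <- discretised_moments(sol$root, sigma)
    if (mom$p[1] > 0.9 || mom$p[7] > 0.9) {
      stop("calibration failure for item ", j, ": target mean ", target,
           " with SD ", sigma, " is degenerate at a scale boundary",
           call. = FALSE)
    }
    latent[j] <- sol$root
    ach_m[j] <- mom$mean
    ach_s[j] <- mom$sd
  }
  structure(
    list(latent_means = latent, latent_sds = cfg$target_sds,
         achieved_means = ach_m, achieved_sds = ach_s,
         target_means = cfg$target_means),
    class = "likert_calibration"
  )
}

#' @export
print.likert_calibration <- function(x, ...) {
  cat("Latent-mean calibration (analytic round-and-clip marginal)\n")
  print(data.frame(
    target_mean = x$target_means,
    latent_mean = round(x$latent_means, 4),
    achieved_mean = round(x$achieved_means, 4),
    latent_sd = x$latent_sds,
    achieved_sd = round(x$achieved_sds, 4)
  ))
  invisible(x)
}

#' Generate correlated 7-point Likert responses
#'
#' Draws a latent multivariate normal with calibrated means, the target
#' SDs, and the configured correlation, then rounds each value to the
#' nearest integer and clips to \[1, 7\]. Identical configurations
#' (including the seed) produce bitwise-identical matrices.
#'
#' @param cfg A `likert_sim_config`.
#' @return An n x 5 integer matrix with columns `item1`..`item5`; the
#'   calibration used is attached as attribute `"calibration"`.
#' @examples
#' head(generate_responses(default_swls_profile(n = 100)))
#' @export
generate_responses <- function(cfg) {
  stopifnot(inherits(cfg, "likert_sim_config"))
  cal <- calibrate_latent_means(cfg)
  d <- cfg$target_sds
  sigma <- diag(d) %*% cfg$corr %*% diag(d)
  # chol of a PSD (possibly singular, e.g. rho = 1) matrix via small jitter
  u <- chol(sigma + diag(1e-12, 5L))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(cfg$seed)
  z <- matrix(stats::rnorm(cfg$n * 5L), nrow = cfg$n, ncol = 5L) %*% u
  lat <- sweep(z, 2L, cal$latent_means, "+")
  resp <- pmin(pmax(round(lat), 1), 7)
  storage.mode(resp) <- "integer"
  colnames(resp) <- paste0("item", 1:5)
  attr(resp, "calibration") <- cal
  resp
}
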
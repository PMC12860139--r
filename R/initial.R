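#' Trial profiles for the modeled population
#'
#' Summary profiles of the three pivotal trial cohorts the model population
#' stands in for: baseline MMD means 10.0 (episodic), 20.4 (chronic) and
#' 14.5 (mixed, inadequate prior response), ~78% female, mean ages spread
#' over 40.0-44.6 years. Trial sizes are not part of the model inputs, so
#' trials are weighted equally by default.
#'
#' @param weights Numeric 3-vector of trial weights; normalized to sum to 1.
#' @return data.frame with columns `trial`, `baseline_mmd_mean`, `weight`,
#'   `female_proportion`, `age_mean`, `age_sd`.
#' @export
trial_profiles <- function(weights = c(1, 1, 1)) {
  if (length(weights) != 3L || any(weights < 0) || sum(weights) <= 0) {
    stop("`weights` must be 3 non-negative values with a positive sum",
         call. = FALSE)
  }
  data.frame(
    trial = c("episodic", "chronic", "mixed"),
    baseline_mmd_mean = c(10.0, 20.4, 14.5),
    weight = weights / sum(weights),
    female_proportion = 0.78,
    age_mean = c(40.0, 42.3, 44.6),
    age_sd = 11.0,
    stringsAsFactors = FALSE
  )
}

# Method-of-moments scaled Beta on [lo, hi] with fixed concentration:
# shape1 + shape2 = concentration, mean matched to the trial mean.
scaled_beta_shapes <- function(mean, concentration, support) {
  lo <- support[1L]; hi <- support[2L]
  mu <- (mean - lo) / (hi - lo)
  if (mu <= 0 || mu >= 1) {
    stop("baseline MMD mean ", mean, " infeasible for Beta support [",
         lo, ", ", hi, "]", call. = FALSE)
  }
  c(shape1 = mu * concentration, shape2 = (1 - mu) * concentration)
}

#' Baseline distribution over MMD bands
#'
#' Derives the cohort's initial state occupancy from the trial baseline MMD
#' means: baseline MMDs follow a mixture of scaled Beta distributions on
#' `support` (trial entry requires at least 4 MMDs), one component per
#' trial, each with its mean fixed to the trial mean. Band membership uses
#' the same half-up rounding as [band_of_mmd()].
#'
#' `method = "analytic"` integrates the mixture density over each band
#' exactly (deterministic); `method = "sample"` draws `n` baseline MMDs and
#' tabulates their bands, which converges to the analytic answer.
#'
#' @param profiles A [trial_profiles()] data.frame.
#' @param concentration Beta concentration (shape1 + shape2); controls the
#'   within-trial spread of baseline MMDs.
#' @param support Range of baseline MMDs, default `c(4, 28)`.
#' @param method `"analytic"` or `"sample"`.
#' @param n,seed Sample size and seed for `method = "sample"`.
#' @return Named numeric 6-vector summing to 1.
#' @export
#' @examples
#' initial_distribution()
initial_distribution <- function(profiles = trial_profiles(),
                                 concentration = 10,
                                 support = c(4, 28),
                                 method = c("analytic", "sample"),
                                 n = 10000, seed = NULL) {
  method <- match.arg(method)
  b <- mmd_bands()
  # band j receives mmd values rounding into [lower, upper]
  cuts <- c(b$lower - 0.5, Inf)
  cuts[1L] <- -Inf
  w <- rep(0, 6L)
  if (method == "analytic") {
    q <- pmin(pmax((cuts - support[1L]) / diff(support), 0), 1)
    for (i in seq_len(nrow(profiles))) {
      sh <- scaled_beta_shapes(profiles$baseline_mmd_mean[i], concentration,
                               support)
      w <- w + profiles$weight[i] * diff(stats::pbeta(q, sh[1L], sh[2L]))
    }
  } else {
    if (!is.null(seed)) set.seed(seed)
    comp <- sample.int(nrow(profiles), n, replace = TRUE, prob = profiles$weight)
    sh <- vapply(profiles$baseline_mmd_mean, scaled_beta_shapes,
                 numeric(2L), concentration = concentration, support = support)
    mmd <- support[1L] + diff(support) *
      stats::rbeta(n, sh[1L, comp], sh[2L, comp])
    w <- as.numeric(table(factor(band_of_mmd(mmd), levels = b$label))) / n
  }
  stats::setNames(w / sum(w), b$label)
}
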
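# Method-of-moments conversions for the standard second-order distributions
# used in health-economic models: Beta for utilities, Gamma for costs,
# Dirichlet for transition rows. sd = 0 is treated as a degenerate
# (point-mass) distribution so that a probabilistic analysis with all
# uncertainty switched off reproduces the deterministic model exactly.

#' Beta parameters from mean and standard deviation
#'
#' @param mean Mean in (0, 1).
#' @param sd Standard deviation; must satisfy `sd^2 < mean * (1 - mean)`.
#' @param what Parameter name used in error messages.
#' @return `c(shape1, shape2)`, or `NULL` for `sd = 0` (degenerate).
#' @export
beta_moments <- function(mean, sd, what = "parameter") {
  if (mean <= 0 || mean >= 1) {
    stop(what, ": Beta mean must lie in (0, 1), got ", mean, call. = FALSE)
  }
  if (sd == 0) return(NULL)
  v <- sd^2
  if (v >= mean * (1 - mean)) {
    stop(what, ": sd ", sd, " too large for Beta with mean ", mean,
         call. = FALSE)
  }
  nu <- mean * (1 - mean) / v - 1
  c(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' Gamma parameters from mean and standard deviation
#'
#' @inheritParams beta_moments
#' @param mean Positive mean.
#' @return `c(shape, rate)`, or `NULL` for `sd = 0` (degenerate).
#' @export
gamma_moments <- function(mean, sd, what = "parameter") {
  if (mean < 0) stop(what, ": Gamma mean must be >= 0", call. = FALSE)
  if (sd == 0 || mean == 0) return(NULL)
  v <- sd^2
  c(shape = mean^2 / v, rate = mean / v)
}

rbeta_ms <- function(n, mean, sd, what = "parameter") {
  sh <- beta_moments(mean, sd, what)
  if (is.null(sh)) return(rep(mean, n))
  stats::rbeta(n, sh[1L], sh[2L])
}

rgamma_ms <- function(n, mean, sd, what = "parameter") {
  sh <- gamma_moments(mean, sd, what)
  if (is.null(sh)) return(rep(mean, n))
  stats::rgamma(n, shape = sh[1L], rate = sh[2L])
}

#' Dirichlet concentration for a transition row from its largest SE
#'
#' Matches the Dirichlet total concentration `nu` to the row entry with the
#' largest standard error via `Var(p_j) = m_j (1 - m_j) / (nu + 1)`, keeping
#' the sampled row on the probability simplex. Structural zeros stay zero.
#'
#' @param mean Row of mean probabilities (sums to 1).
#' @param se Row of standard errors.
#' @return Total concentration (a positive scalar), or `Inf` when all SEs
#'   are zero (degenerate row).
#' @export
dirichlet_concentration <- function(mean, se) {
  use <- mean > 0 & mean < 1 & se > 0
  if (!any(use)) return(Inf)
  j <- which(use)[which.max(se[use])]
  nu <- mean[j] * (1 - mean[j]) / se[j]^2 - 1
  if (nu <= 0) {
    stop("standard error ", signif(se[j], 3), " too large for probability ",
         signif(mean[j], 3), "; no feasible Dirichlet concentration",
         call. = FALSE)
  }
  nu
}

# n draws of a Dirichlet row via independent Gammas; shape-0 components are
# structural zeros. Returns an n x 6 matrix.
rdirichlet_row <- function(n, mean, nu) {
  if (!is.finite(nu)) {
    return(matrix(mean, n, length(mean), byrow = TRUE))
  }
  g <- matrix(stats::rgamma(n * length(mean), shape = rep(mean * nu, each = n)),
              nrow = n)
  g / rowSums(g)
}
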
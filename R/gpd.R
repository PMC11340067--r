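#' The generalized Poisson distribution
#'
#' Density (probability mass), random generation, moments and support bound
#' for the Consul–Jain generalized Poisson (GP) distribution in its
#' mean/dispersion-factor parametrization.  The distribution has mean
#' \eqn{\mu} and variance \eqn{\vartheta^2 \mu}: `theta` (\eqn{\vartheta}) is
#' the dispersion *factor*, the square root of the variance-to-mean ratio.
#' `theta = 1` recovers the Poisson distribution exactly; `theta > 1` gives
#' over-dispersion and `theta < 1` under-dispersion, in which case the
#' support is truncated at the bound returned by [gp_support_bound()] and
#' the mass is *not* renormalized (the small missing mass can be inspected
#' with [gp_mass_deficit()]).
#'
#' The probability mass at a non-negative integer \eqn{y} is
#' \deqn{P(Y=y) = \mu\,[\mu + (\vartheta-1)y]^{y-1}\,
#'   \frac{\vartheta^{-y}}{y!}\,
#'   \exp\{-[\mu + (\vartheta-1)y]/\vartheta\},}
#' for \eqn{y} in the support, and 0 for \eqn{y > m} when
#' \eqn{\vartheta < 1}, where \eqn{m} is the largest integer with
#' \eqn{\mu + m(\vartheta - 1) > 0}.  Feasible parameters satisfy
#' \eqn{\mu > 0} and \eqn{\vartheta \ge \max(1/2,\; 1 - \mu/4)}.
#'
#' Computation is carried out in log space with `lgamma`; exponentiation
#' happens only at the interface.
#'
#' @param x vector of non-negative integer quantiles.
#' @param n number of draws.
#' @param mu mean parameter \eqn{\mu > 0}; recycled against `x` (for
#'   `rgpois`, a vector of length 1 or `n`).
#' @param theta dispersion factor \eqn{\vartheta}; recycled likewise.
#' @param log logical; if `TRUE`, log-probabilities are returned.
#' @param cap highest count considered when inverting the cumulative pmf in
#'   `rgpois`.  Defaults to `mu + 50 * theta * sqrt(mu) + 100`, far beyond
#'   any appreciable mass; a draw that would exceed the cap is truncated to
#'   it with a warning.
#'
#' @return `dgpois` a numeric vector of (log-)probabilities; `rgpois` an
#'   integer-valued numeric vector of draws.
#'
#' @examples
#' dgpois(0:5, mu = 4, theta = 2)
#' all.equal(dgpois(0:20, mu = 3, theta = 1), dpois(0:20, 3))
#' x <- rgpois(1000, mu = 4, theta = 2, seed = 1)
#' var(x) / mean(x)   # close to theta^2 = 4
#' @export
dgpois <- function(x, mu, theta, log = FALSE) {
  check_gp_params(mu, theta)
  if (any(x < 0 | x != floor(x))) {
    stop("`x` must contain non-negative integers", call. = FALSE)
  }
  k <- max(length(x), length(mu), length(theta))
  x <- rep_len(x, k)
  mu <- rep_len(mu, k)
  theta <- rep_len(theta, k)

  lam <- mu + (theta - 1) * x          # must be > 0 inside the support
  out <- rep(-Inf, k)
  ok <- lam > 0
  out[ok] <- log(mu[ok]) + (x[ok] - 1) * log(lam[ok]) -
    x[ok] * log(theta[ok]) - lgamma(x[ok] + 1) - lam[ok] / theta[ok]
  # beyond the truncation bound (theta < 1) the pmf is defined as zero
  if (log) out else exp(out)
}

#' @rdname dgpois
#' @param seed optional integer; when supplied the draw is made under a
#'   private RNG state so the same seed always yields the same sequence and
#'   the caller's RNG is untouched.
#' @export
rgpois <- function(n, mu, theta, cap = NULL, seed = NULL) {
  check_gp_params(mu, theta)
  if (!is.null(seed)) {
    return(with_seed(seed, rgpois(n, mu, theta, cap = cap)))
  }
  k <- length(mu)
  if (!k %in% c(1L, n) || length(theta) != length(mu)) {
    mu <- rep_len(mu, n)
    theta <- rep_len(theta, n)
  }
  if (length(mu) == 1L) {
    cdf <- gp_cdf_table(mu, theta, cap)
    u <- runif(n)
    over <- u > cdf[length(cdf)]
    if (any(over)) {
      warning("rgpois: ", sum(over), " draw(s) exceeded the inversion cap ",
              length(cdf) - 1L, " and were truncated to it")
    }
    return(findInterval(u, cdf))
  }
  u <- runif(n)
  out <- numeric(n)
  n_over <- 0L
  for (i in seq_len(n)) {
    cdf <- gp_cdf_table(mu[i], theta[i], cap)
    if (u[i] > cdf[length(cdf)]) n_over <- n_over + 1L
    out[i] <- findInterval(u[i], cdf)
  }
  if (n_over > 0L) {
    warning("rgpois: ", n_over, " draw(s) exceeded the inversion cap and were truncated")
  }
  out
}

# Cumulative pmf over 0..cap for scalar (mu, theta).
gp_cdf_table <- function(mu, theta, cap = NULL) {
  cap <- cap %||% ceiling(mu + 50 * theta * sqrt(mu) + 100)
  m <- gp_support_bound(mu, theta)
  if (is.finite(m)) cap <- min(cap, m)
  cumsum(dgpois(0:cap, mu, theta))
}

#' Convert between GP parametrizations
#'
#' The natural Consul–Jain parametrization \eqn{(\alpha, \delta)} with
#' \eqn{\alpha > 0}, \eqn{\delta < 1} relates to the mean parametrization by
#' \eqn{\mu = \alpha / (1 - \delta) = \vartheta\alpha} and
#' \eqn{\vartheta = 1 / (1 - \delta)}; \eqn{\delta = 0} (\eqn{\vartheta = 1})
#' is the Poisson case, \eqn{\delta < 0} under-dispersion.
#'
#' @param alpha rate-like natural parameter, \eqn{\alpha > 0}.
#' @param delta dispersion parameter, \eqn{\delta < 1}.
#' @param mu,theta mean parametrization (see [dgpois()]).
#' @return A named list with the parameters of the other parametrization.
#' @examples
#' gp_natural_to_mean(alpha = 2, delta = 0.5)   # mu 4, theta 2
#' gp_mean_to_natural(mu = 4, theta = 2)
#' @export
gp_natural_to_mean <- function(alpha, delta) {
  if (any(alpha <= 0)) stop("`alpha` must be positive", call. = FALSE)
  if (any(delta >= 1)) stop("`delta` must be < 1", call. = FALSE)
  list(mu = alpha / (1 - delta), theta = 1 / (1 - delta))
}

#' @rdname gp_natural_to_mean
#' @export
gp_mean_to_natural <- function(mu, theta) {
  check_gp_params(mu, theta)
  list(alpha = mu / theta, delta = 1 - 1 / theta)
}

#' GP moments, support bound and truncation mass
#'
#' `gp_moments` returns the mean \eqn{\mu} and variance
#' \eqn{\vartheta^2\mu}.  `gp_support_bound` returns, for an
#' under-dispersed GP (\eqn{\vartheta < 1}), the largest integer \eqn{m}
#' with \eqn{\mu + m(\vartheta - 1) > 0} — the last count carrying positive
#' probability — and `Inf` when \eqn{\vartheta \ge 1} (unbounded support).
#' `gp_mass_deficit` reports the signed shortfall
#' \eqn{1 - \sum_{y} P(Y=y)} over the (possibly truncated) support: the
#' pmf is not renormalized under under-dispersion, and the truncated total
#' can fall slightly below *or* above one; this diagnostic quantifies the
#' discrepancy (it is numerically zero for \eqn{\vartheta \ge 1}).
#'
#' @inheritParams dgpois
#' @return `gp_moments` a list with `mean` and `variance`;
#'   `gp_support_bound` a number (integer or `Inf`); `gp_mass_deficit`
#'   a single small number (positive when mass is lost).
#' @examples
#' gp_moments(mu = 4, theta = 2)          # mean 4, variance 16
#' gp_support_bound(mu = 4, theta = 0.5)  # 7
#' gp_mass_deficit(mu = 4, theta = 0.5)
#' @export
gp_moments <- function(mu, theta) {
  check_gp_params(mu, theta)
  list(mean = mu, variance = theta^2 * mu)
}

#' @rdname gp_moments
#' @export
gp_support_bound <- function(mu, theta) {
  check_gp_params(mu, theta)
  if (theta >= 1) return(Inf)
  # largest integer m with mu + m*(theta - 1) > 0, i.e. m strictly below
  # mu / (1 - theta); the small tolerance keeps exact boundaries (where the
  # ratio is an integer up to rounding noise) excluded
  r <- mu / (1 - theta)
  ceiling(r - 1e-9) - 1
}

#' @rdname gp_moments
#' @export
gp_mass_deficit <- function(mu, theta, cap = NULL) {
  check_gp_params(mu, theta)
  cdf <- gp_cdf_table(mu, theta, cap)
  1 - cdf[length(cdf)]
}

# Parameter feasibility: mu > 0 and theta >= max(1/2, 1 - mu/4).
check_gp_params <- function(mu, theta) {
  if (any(!is.finite(mu)) || any(mu <= 0)) {
    stop("GP parameter `mu` must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(theta)) || any(theta < pmax(0.5, 1 - mu / 4))) {
    stop("GP parameter `theta` must satisfy theta >= max(1/2, 1 - mu/4)",
         call. = FALSE)
  }
  invisible(TRUE)
}

gp_feasible <- function(mu, theta) {
  all(is.finite(mu)) && all(mu > 0) && all(is.finite(theta)) &&
    all(theta >= pmax(0.5, 1 - mu / 4))
}
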
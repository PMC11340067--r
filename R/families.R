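# Count-family abstraction shared by the likelihood, sampler and Pearson
# diagnostic code.  Each family provides its log-pmf, mean-variance
# relation and sampler in the (mu, dispersion) parametrization used for
# regression: GP carries the dispersion factor theta (variance theta^2*mu),
# NB2 carries alpha (variance mu + mu^2/alpha), Poisson has no dispersion
# parameter.  Poisson and NB2 pmfs delegate to the standard stats
# implementations; the GP pmf is the package's own.

COUNT_FAMILIES <- c("poisson", "nb", "gp")

match_family <- function(family) {
  match.arg(tolower(family), COUNT_FAMILIES)
}

family_n_disp <- function(family) {
  if (match_family(family) == "poisson") 0L else 1L
}

family_logpmf <- function(family, y, mu, disp = NULL) {
  switch(match_family(family),
    poisson = dpois(y, lambda = mu, log = TRUE),
    nb = dnbinom(y, size = disp, mu = mu, log = TRUE),
    gp = dgpois(y, mu = mu, theta = disp, log = TRUE)
  )
}

family_variance <- function(family, mu, disp = NULL) {
  switch(match_family(family),
    poisson = mu,
    nb = mu + mu^2 / disp,
    gp = disp^2 * mu
  )
}

#' Draw i.i.d. counts from a fitted-family law
#'
#' Seeded sampler for the three regression families.  `mu` may be a scalar
#' or a vector of length `n` (per-observation means under a log link);
#' the dispersion is `theta` for the GP family, `alpha` (NB2 size) for the
#' negative binomial, and ignored for Poisson.  GP draws are made by
#' inversion of the cumulative pmf (see [rgpois()]).
#'
#' @param family one of `"poisson"`, `"nb"`, `"gp"`.
#' @param n number of draws.
#' @param mu mean(s), positive.
#' @param disp dispersion parameter (GP `theta` or NB `alpha`); required
#'   for those families.
#' @param seed integer seed; the same seed always reproduces the same
#'   sequence and the caller's RNG state is left untouched.
#' @return numeric vector of `n` non-negative integers.
#' @examples
#' sample_counts("gp", 10, mu = 4, disp = 2, seed = 42)
#' @export
sample_counts <- function(family, n, mu, disp = NULL, seed = NULL) {
  family <- match_family(family)
  if (n < 1) stop("`n` must be at least 1", call. = FALSE)
  if (any(mu <= 0)) stop("`mu` must be positive", call. = FALSE)
  if (family != "poisson") {
    if (is.null(disp)) stop("`disp` is required for family '", family, "'",
                            call. = FALSE)
    if (family == "nb" && any(disp <= 0)) {
      stop("NB dispersion `alpha` must be positive", call. = FALSE)
    }
  }
  draw <- function() {
    switch(family,
      poisson = rpois(n, lambda = rep_len(mu, n)),
      nb = rnbinom(n, size = disp, mu = rep_len(mu, n)),
      gp = rgpois(n, mu = mu, theta = disp)
    )
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# ---- negative log-likelihood and analytic gradients --------------------

#' Negative log-likelihood of a count regression
#'
#' Evaluates \eqn{-\sum_i \log f(y_i;\, \mu_i, \mathrm{disp})} with
#' \eqn{\mu_i = \exp(x_i'\beta)} under the chosen family.  The dispersion is
#' passed on its estimation (log) scale: `log(theta)` for GP, `log(alpha)`
#' for NB2, and must be omitted (`numeric(0)`) for Poisson.  Parameter
#' points that are infeasible — a non-finite linear predictor, or a GP
#' dispersion violating \eqn{\vartheta \ge \max(1/2, 1-\mu_i/4)} for any
#' observation — return `+Inf` so optimizers simply reject them.
#'
#' @param family one of `"poisson"`, `"nb"`, `"gp"`.
#' @param beta coefficient vector conformable with `X`.
#' @param log_disp dispersion on the log scale (length 1, or 0 for Poisson).
#' @param X numeric design matrix (n x k).
#' @param y non-negative integer response vector.
#' @return a single number (possibly `Inf`).
#' @export
negloglik_count <- function(family, beta, log_disp = numeric(0), X, y) {
  family <- match_family(family)
  if (ncol(X) != length(beta)) stop("`beta` does not match ncol(X)", call. = FALSE)
  if (nrow(X) != length(y)) stop("`y` does not match nrow(X)", call. = FALSE)
  if (length(log_disp) != family_n_disp(family)) {
    stop("`log_disp` must have length ", family_n_disp(family),
         " for family '", family, "'", call. = FALSE)
  }
  eta <- drop(X %*% beta)
  if (any(!is.finite(eta)) || any(eta > 700)) return(Inf)
  mu <- exp(eta)
  if (family == "poisson") {
    return(-sum(dpois(y, mu, log = TRUE)))
  }
  disp <- exp(log_disp)
  if (!is.finite(disp) || disp <= 0) return(Inf)
  if (family == "nb") {
    return(-sum(dnbinom(y, size = disp, mu = mu, log = TRUE)))
  }
  # gp
  if (!gp_feasible(mu, disp)) return(Inf)
  lam <- mu + (disp - 1) * y
  if (any(lam <= 0)) return(Inf)
  ll <- log(mu) + (y - 1) * log(lam) - y * log(disp) - lgamma(y + 1) - lam / disp
  -sum(ll)
}

# Gradient of negloglik_count w.r.t. c(beta, log_disp); analytic.
# Returns NULL at infeasible points.
negloglik_grad <- function(family, beta, log_disp = numeric(0), X, y) {
  family <- match_family(family)
  eta <- drop(X %*% beta)
  if (any(!is.finite(eta)) || any(eta > 700)) return(NULL)
  mu <- exp(eta)
  if (family == "poisson") {
    return(-drop(crossprod(X, y - mu)))
  }
  disp <- exp(log_disp)
  if (!is.finite(disp) || disp <= 0) return(NULL)
  if (family == "nb") {
    a <- disp
    dl_dmu <- y / mu - (y + a) / (a + mu)
    g_beta <- drop(crossprod(X, dl_dmu * mu))
    dl_da <- digamma(a + y) - digamma(a) + log(a) + 1 -
      log(a + mu) - (y + a) / (a + mu)
    return(-c(g_beta, sum(dl_da) * a))   # chain rule for log(alpha)
  }
  # gp
  th <- disp
  if (!gp_feasible(mu, th)) return(NULL)
  lam <- mu + (th - 1) * y
  if (any(lam <= 0)) return(NULL)
  dl_dmu <- 1 / mu + (y - 1) / lam - 1 / th
  g_beta <- drop(crossprod(X, dl_dmu * mu))
  dl_dth <- (y - 1) * y / lam - 2 * y / th + lam / th^2
  -c(g_beta, sum(dl_dth) * th)           # chain rule for log(theta)
}
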
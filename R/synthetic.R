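#' Configure the synthetic council-data generator
#'
#' Builds the generator "truth": the coefficient vector on the design
#' scale, the count family and dispersion, the covariate laws, the
#' categorical level frequencies and the missingness rate.  Defaults
#' emulate the structure of the 2020 Tanzania mainland council dataset
#' the analysis targets: 184 councils across seven zones (frequencies
#' matching the published zone margins), an urban share of 45/184,
#' right-skewed population and GDP (log-normal), a small gamma-tailed
#' HIV-prevalence percentage, a near-symmetric male share, and counts
#' drawn from a generalized Poisson law with log-link mean
#' \eqn{\exp(x'\beta)} and strong over-dispersion.  The default `beta_true`
#' is the published GP coefficient vector, so synthetic data echo the
#' study's effect pattern (urban excess, northern-zone reference excess).
#'
#' Continuous covariates are generated directly on the design (transformed)
#' scale — `population` and `gdp` enter the design as logs — and the raw
#' scale is emitted too, so the transform pipeline is exercised.
#'
#' @param n_councils number of councils (default 184).
#' @param zone_probs named 7-vector of zone probabilities (sums to 1).
#' @param urban_prob probability a council is Urban (default 45/184).
#' @param beta_true named 13-vector of design-scale coefficients.
#' @param family count family for the response (default `"gp"`).
#' @param dispersion GP `theta` or NB `alpha` (default `exp(1.4443)`,
#'   about 4.24: strong over-dispersion).
#' @param covariate_params list of law parameters for the continuous
#'   covariates (see defaults in the function signature for the shape).
#' @param age_split_prob probability a case falls in the 5–59 band when
#'   the council total is split between the two age bands.
#' @param missing_rate probability a council's counts are missing
#'   (default 7/184, giving about 177 complete cases).
#' @param seed integer seed stored in the config; [generate_councils()] is
#'   fully deterministic given the config.
#' @return an object of class `"synth_config"`.
#' @examples
#' cfg <- synth_config(seed = 1)
#' cfg$beta_true[["residenceUrban"]]
#' @export
synth_config <- function(n_councils = 184,
                         zone_probs = NULL,
                         urban_prob = 45 / 184,
                         beta_true = NULL,
                         family = "gp",
                         dispersion = exp(1.4443),
                         covariate_params = NULL,
                         age_split_prob = 0.5,
                         missing_rate = 7 / 184,
                         seed = 1L) {
  family <- match_family(family)
  zone_probs <- zone_probs %||% default_zone_probs()
  if (length(zone_probs) != 7L || abs(sum(zone_probs) - 1) > 1e-8 ||
      any(zone_probs < 0)) {
    stop("`zone_probs` must be 7 non-negative probabilities summing to 1",
         call. = FALSE)
  }
  if (is.null(names(zone_probs))) names(zone_probs) <- zone_levels()
  stopifnot_scalar_prob(urban_prob, "urban_prob")
  stopifnot_scalar_prob(missing_rate, "missing_rate")
  stopifnot_scalar_prob(age_split_prob, "age_split_prob")
  beta_true <- beta_true %||% default_beta_true()
  if (length(beta_true) != 13L) stop("`beta_true` must have length 13", call. = FALSE)
  if (is.null(names(beta_true))) names(beta_true) <- design_colnames()
  if (family != "poisson" && (!is.numeric(dispersion) || dispersion <= 0)) {
    stop("`dispersion` must be positive", call. = FALSE)
  }
  covariate_params <- covariate_params %||% list(
    pplhiv_pct = list(shape = 2, scale = 1.25),        # gamma, mean 2.5%
    log_population = list(mean = 12.0, sd = 0.7),      # ~160k median
    log_gdp = list(mean = 13.0, sd = 0.8),
    n_facilities = list(size = 5, mu = 30),            # NB: skewed counts
    pct_male = list(shape1 = 8, shape2 = 8)            # 100*Beta, mean 50
  )
  structure(
    list(n_councils = as.integer(n_councils), zone_probs = zone_probs,
         urban_prob = urban_prob, beta_true = beta_true, family = family,
         dispersion = if (family == "poisson") NA_real_ else dispersion,
         covariate_params = covariate_params,
         age_split_prob = age_split_prob,
         missing_rate = missing_rate, seed = as.integer(seed)),
    class = "synth_config"
  )
}

# Zone frequencies from the published zone margins (x/184).
default_zone_probs <- function() {
  p <- c(Northern = 31, Central = 15, Eastern = 24, Lake = 36, Southern = 23,
         `Southern Highlands` = 32, Western = 23) / 184
  p[zone_levels()]
}

design_colnames <- function() {
  c("(Intercept)", "pplhiv_pct", "population", "gdp", "n_facilities",
    "pct_male", "residenceUrban", paste0("zone", zone_levels()[-1]))
}

# Published GP coefficient vector, in design-column order.
default_beta_true <- function() {
  setNames(
    c(3.5400, 0.0616, 0.2264, -0.1507, 0.0132, -0.0017, 1.1720,
      -0.8480, -0.6483, -0.7265, -0.8064, -0.7467, -0.3392),
    design_colnames()
  )
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic council-data configuration\n")
  cat("  councils:", x$n_councils, " family:", x$family,
      " dispersion:", format(x$dispersion, digits = 4),
      " missing rate:", format(x$missing_rate, digits = 3), "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Generate a synthetic council dataset
#'
#' Draws covariates from the configured laws, computes per-council means
#' \eqn{\mu_i = \exp(x_i'\beta_{true})} on the design scale, samples the
#' council's total count from the configured family, splits it between the
#' two age bands binomially, and applies independent missingness.  The
#' same config (including its seed) always yields a byte-identical
#' dataset.  The generator truth is returned alongside the records for
#' parameter-recovery testing.
#'
#' @param config a [synth_config()].
#' @return a list with `records` (a council data frame with the standard
#'   schema) and `truth` (see [truth_report()]).
#' @examples
#' out <- generate_councils(synth_config(n_councils = 50, seed = 3))
#' head(out$records)
#' @export
generate_councils <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_councils
  cp <- config$covariate_params
  with_seed(config$seed, {
    zone <- sample(names(config$zone_probs), n, replace = TRUE,
                   prob = config$zone_probs)
    residence <- ifelse(runif(n) < config$urban_prob, "Urban", "Rural")
    pplhiv <- rgamma(n, shape = cp$pplhiv_pct$shape, scale = cp$pplhiv_pct$scale)
    log_pop <- rnorm(n, cp$log_population$mean, cp$log_population$sd)
    log_gdp <- rnorm(n, cp$log_gdp$mean, cp$log_gdp$sd)
    fac <- rnbinom(n, size = cp$n_facilities$size, mu = cp$n_facilities$mu)
    pmale <- 100 * rbeta(n, cp$pct_male$shape1, cp$pct_male$shape2)

    X <- cbind(
      1, pplhiv, log_pop, log_gdp, fac, pmale,
      as.numeric(residence == "Urban"),
      vapply(zone_levels()[-1], function(z) as.numeric(zone == z), numeric(n))
    )
    colnames(X) <- design_colnames()
    mu <- exp(drop(X %*% config$beta_true))
    if (config$family == "gp" && !gp_feasible(mu, config$dispersion)) {
      stop("infeasible (mu, theta) combination implied by the config",
           call. = FALSE)
    }
    total <- switch(config$family,
      poisson = rpois(n, mu),
      nb = rnbinom(n, size = config$dispersion, mu = mu),
      gp = rgpois(n, mu = mu, theta = config$dispersion)
    )
    young <- rbinom(n, size = total, prob = config$age_split_prob)
    miss <- runif(n) < config$missing_rate

    records <- data.frame(
      council_id = sprintf("C%03d", seq_len(n)),
      zone = zone, residence = residence,
      pplhiv_pct = pplhiv,
      population = exp(log_pop), gdp = exp(log_gdp),
      n_facilities = fac, pct_male = pmale,
      count_5_59 = ifelse(miss, NA_integer_, young),
      count_60plus = ifelse(miss, NA_integer_, total - young),
      stringsAsFactors = FALSE
    )
    list(records = records, truth = truth_report(config))
  })
}

#' Generator truth record
#'
#' Echoes the parameters that produced a synthetic dataset — the target of
#' parameter-recovery tests.  Round-trips through JSON unchanged.
#'
#' @param config a [synth_config()].
#' @return a list with `beta_true`, `family`, `dispersion`, `transforms`,
#'   `response`, `n_councils`, `seed`.
#' @export
truth_report <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  list(
    beta_true = config$beta_true,
    family = config$family,
    dispersion = config$dispersion,
    transforms = list(population = "log", gdp = "log"),
    response = "total",
    n_councils = config$n_councils,
    seed = config$seed
  )
}
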
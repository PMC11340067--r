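# Synthetic council-data generator: defaults, determinism, distributional
# structure, truth reporting, parameter recovery.

test_that("default configuration encodes the study structure", {
  cfg <- synth_config(seed = 1)
  expect_equal(cfg$n_councils, 184L)
  expect_equal(cfg$urban_prob, 45 / 184)
  expect_equal(sum(cfg$zone_probs), 1)
  expect_equal(length(cfg$beta_true), 13)
  expect_equal(unname(cfg$beta_true["residenceUrban"]), 1.1720)
  expect_equal(unname(cfg$beta_true["(Intercept)"]), 3.5400)
  expect_gt(cfg$dispersion, 1)          # strong over-dispersion by default
  expect_equal(cfg$missing_rate, 7 / 184)
})

test_that("generation is fully seed-deterministic", {
  cfg <- synth_config(seed = 42)
  a <- generate_councils(cfg)
  b <- generate_councils(cfg)
  expect_identical(a, b)
  c <- generate_councils(synth_config(seed = 43))
  expect_false(identical(a$records$count_5_59, c$records$count_5_59))
  # and leaves the caller's RNG stream untouched
  set.seed(7); x1 <- runif(1)
  set.seed(7); invisible(generate_councils(cfg)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("records carry the full schema with valid levels and counts", {
  r <- generate_councils(synth_config(seed = 3))$records
  expect_equal(nrow(r), 184)
  expect_true(all(council_columns() %in% names(r)))
  expect_true(all(r$zone %in% zone_levels()))
  expect_true(all(r$residence %in% residence_levels()))
  ok <- !is.na(r$count_5_59)
  expect_true(all(r$count_5_59[ok] >= 0 & r$count_5_59[ok] == floor(r$count_5_59[ok])))
  expect_true(all(r$population > 0 & r$gdp > 0))
  expect_true(all(r$pct_male >= 0 & r$pct_male <= 100))
})

test_that("generated counts are over-dispersed and right-skewed under gp defaults", {
  r <- generate_councils(synth_config(seed = 5))$records
  total <- r$count_5_59 + r$count_60plus
  s <- dispersion_summary(total[!is.na(total)])
  expect_gt(s$ratio, 1)
  expect_gt(s$skewness, 0)
})

test_that("missingness yields the expected complete-case count", {
  miss <- vapply(1:20, function(s) {
    sum(is.na(generate_councils(synth_config(seed = s))$records$count_5_59))
  }, 0)
  # binomial(184, 7/184): mean 7, sd 2.6; the average over 20 replicates
  # should sit well within 4 standard errors
  expect_lt(abs(mean(miss) - 7), 4 * 2.6 / sqrt(20))
})

test_that("categorical frequencies sit in their binomial 99% bands", {
  r <- generate_councils(synth_config(seed = 8))$records
  n <- nrow(r)
  p <- 45 / 184
  urban <- sum(r$residence == "Urban")
  band <- 2.58 * sqrt(n * p * (1 - p))
  expect_lt(abs(urban - n * p), band + 1)
  zp <- synth_config(seed = 8)$zone_probs
  for (z in names(zp)) {
    obs <- sum(r$zone == z)
    expect_lt(abs(obs - n * zp[[z]]),
              2.58 * sqrt(n * zp[[z]] * (1 - zp[[z]])) + 1)
  }
})

test_that("empirical count mean tracks the configured design truth", {
  cfg <- synth_config(seed = 12, missing_rate = 0)
  out <- generate_councils(cfg)
  d <- build_design(out$records)
  mu <- exp(drop(d$X %*% cfg$beta_true))
  total <- d$y
  # Monte-Carlo SE of the mean under GP: theta * sqrt(mean mu / n)
  se <- cfg$dispersion * sqrt(mean(mu) / length(mu))
  expect_lt(abs(mean(total) - mean(mu)), 4 * se)
})

test_that("truth report round-trips through JSON and matches the config", {
  cfg <- synth_config(seed = 2)
  tr <- truth_report(cfg)
  expect_equal(length(tr$beta_true), 13)
  expect_equal(tr$family, "gp")
  json <- jsonlite::toJSON(tr, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::fromJSON(json)
  expect_equal(unname(unlist(back$beta_true)), unname(tr$beta_true))
  expect_equal(back$dispersion, tr$dispersion)
})

test_that("gp fit on a large synthetic dataset recovers the generator truth", {
  cfg <- synth_config(n_councils = 5000, seed = 17, missing_rate = 0)
  out <- generate_councils(cfg)
  d <- build_design(out$records)
  f <- fit_count_model(d, family = "gp")
  expect_true(f$converged)
  truth <- c(cfg$beta_true, log(cfg$dispersion))
  within3 <- abs(coef(f) - truth) <= 3 * f$std_errors
  expect_gte(sum(within3), 12)   # at least 12 of the 14 parameters
})

test_that("infeasible configurations are rejected before sampling", {
  expect_error(synth_config(dispersion = -2), "positive")
  expect_error(synth_config(zone_probs = rep(1, 7)), "summing")
  expect_error(synth_config(missing_rate = 1.5), "probability")
})
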
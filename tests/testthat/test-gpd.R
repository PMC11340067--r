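# Generalized Poisson distribution: pmf, parametrizations, moments,
# truncation, sampler.

test_that("gp pmf matches closed-form anchor points and reduces to Poisson", {
  # y = 0 collapses the pmf to exp(-mu/theta)
  expect_equal(dgpois(0, mu = 4, theta = 2, log = TRUE), -2)
  expect_equal(dgpois(0, 4, 2), exp(-2), tolerance = 1e-12)

  # theta = 1 is exactly Poisson, pointwise
  for (mu in c(0.5, 2, 10)) {
    expect_equal(dgpois(0:50, mu, theta = 1, log = TRUE),
                 dpois(0:50, mu, log = TRUE), tolerance = 1e-12)
  }
  expect_equal(dgpois(3, 2, 1), exp(-2) * 2^3 / 6, tolerance = 1e-12)
})

test_that("gp pmf is a normalized probability mass function when theta >= 1", {
  expect_equal(sum(dgpois(0:1000, mu = 4, theta = 2)), 1, tolerance = 1e-10)
  for (p in list(c(0.5, 1), c(2, 1.5), c(10, 3), c(4, 2))) {
    cap <- ceiling(p[1] + 50 * p[2] * sqrt(p[1])) + 50
    s <- sum(dgpois(0:cap, p[1], p[2]))
    expect_gte(s, 1 - 1e-8)
    expect_lte(s, 1 + 1e-8)
    expect_true(all(dgpois(0:cap, p[1], p[2]) >= 0))
    expect_true(all(dgpois(0:cap, p[1], p[2]) <= 1))
  }
})

test_that("parametrization conversions match the moment formulas and round-trip", {
  expect_equal(gp_natural_to_mean(2, 0.5), list(mu = 4, theta = 2))
  expect_equal(gp_natural_to_mean(3, 0), list(mu = 3, theta = 1))
  back <- do.call(gp_natural_to_mean, gp_mean_to_natural(7.3, 1.8))
  expect_equal(back, list(mu = 7.3, theta = 1.8))
  expect_error(gp_natural_to_mean(2, 1.2), "delta")
  expect_error(gp_mean_to_natural(-1, 2), "mu")
})

test_that("moments are mu and theta^2 * mu", {
  expect_equal(gp_moments(4, 2), list(mean = 4, variance = 16))
  expect_equal(gp_moments(5, 1), list(mean = 5, variance = 5))
  # distributional check: mean/variance of the pmf itself
  y <- 0:600
  p <- dgpois(y, 6, 2.5)
  expect_equal(sum(y * p), 6, tolerance = 1e-8)
  expect_equal(sum((y - 6)^2 * p), 2.5^2 * 6, tolerance = 1e-6)
})

test_that("support bound solves mu + m(theta-1) > 0 and truncation zeroes the tail", {
  expect_identical(gp_support_bound(4, 2), Inf)
  expect_equal(gp_support_bound(4, 0.5), 7)
  expect_equal(gp_support_bound(2, 0.9), 19)
  # enumeration oracle
  for (p in list(c(4, 0.5), c(2, 0.9), c(3, 0.6))) {
    m_true <- max(Filter(function(m) p[1] + m * (p[2] - 1) > 1e-12, 0:1000))
    expect_equal(gp_support_bound(p[1], p[2]), m_true)
  }
  m <- gp_support_bound(4, 0.5)
  expect_true(all(dgpois((m + 1):(m + 20), 4, 0.5) == 0))
  expect_true(all(dgpois(0:m, 4, 0.5) > 0))
})

test_that("truncated mass is not renormalized but stays near one", {
  for (p in list(c(4, 0.5), c(2, 0.9), c(6, 0.7))) {
    expect_lt(abs(gp_mass_deficit(p[1], p[2])), 0.01)
  }
  expect_equal(gp_mass_deficit(4, 2), 0, tolerance = 1e-8)
})

test_that("infeasible parameters are rejected", {
  expect_error(dgpois(1, mu = -1, theta = 2), "mu")
  expect_error(dgpois(1, mu = 4, theta = 0.4), "theta")
  expect_error(dgpois(1, mu = 1, theta = 0.6), "theta")  # 1 - mu/4 = 0.75
  expect_error(dgpois(1.5, mu = 4, theta = 2), "integer")
  expect_silent(dgpois(1, mu = 4, theta = 0.5))          # boundary is allowed
})

test_that("gp sampler is seed-deterministic and matches its moments", {
  a <- rgpois(50, 4, 2, seed = 99)
  b <- rgpois(50, 4, 2, seed = 99)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a == floor(a)))

  x <- rgpois(1e5, 4, 2, seed = 7)
  expect_equal(var(x) / mean(x), 4, tolerance = 0.05)
  # empirical moments within 4 Monte-Carlo SEs for several settings
  for (p in list(c(4, 2), c(2, 1.5), c(10, 3))) {
    x <- rgpois(2e4, p[1], p[2], seed = 11)
    se_mean <- p[2] * sqrt(p[1]) / sqrt(2e4)
    expect_lt(abs(mean(x) - p[1]), 4 * se_mean)
    # SE of the sample variance ~ sqrt(2/n)*sigma^2 (normal approx, inflated)
    expect_lt(abs(var(x) - p[2]^2 * p[1]), 8 * sqrt(2 / 2e4) * p[2]^2 * p[1])
  }
})

test_that("gp sampler accepts per-observation means", {
  mu <- c(2, 5, 20, 100)
  x <- rgpois(4, mu, 2, seed = 5)
  expect_length(x, 4)
  # large samples per mean match the mean
  for (m in mu) {
    x <- rgpois(2e4, m, 2, seed = 5)
    expect_equal(mean(x), m, tolerance = 0.1)
  }
})
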
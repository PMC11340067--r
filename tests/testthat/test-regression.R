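# Design construction, maximum-likelihood fitting, Wald inference,
# prediction.

test_that("full council specification yields the 13-column design", {
  r <- small_records(100)
  d <- build_design(r)
  expect_equal(ncol(d$X), 13)
  expect_equal(colnames(d$X)[1], "(Intercept)")
  expect_true(all(d$X[, 1] == 1))
  dummies <- d$X[, 7:13]
  expect_true(all(dummies %in% c(0, 1)))
  # reference-level rows have all dummies zero
  ref <- r$residence == "Rural" & r$zone == "Northern"
  expect_true(all(dummies[ref, ] == 0))
  expect_equal(d$n_used, 100)
})

test_that("complete-case handling drops and reports missing rows", {
  r <- small_records(60)
  r$count_5_59[c(3, 10, 44)] <- NA
  d <- build_design(r)
  expect_equal(d$n_used, 57)
  expect_setequal(d$dropped_rows, r$council_id[c(3, 10, 44)])
  r$count_5_59 <- NA
  expect_error(build_design(r), "complete cases")
})

test_that("schema violations are caught by name", {
  r <- small_records(30)
  r$zone[5] <- "Coastal"
  expect_error(build_design(r), "Coastal")
  r <- small_records(30)
  r$gdp[2] <- -1
  expect_error(build_design(r), "gdp")
})

test_that("intercept-only Poisson MLE is log(ybar)", {
  y <- c(0, 3, 5, 2, 2, 8, 1, 4)
  f <- fit_count_model(matrix(1, length(y), 1), y, family = "poisson")
  expect_true(f$converged)
  expect_equal(unname(coef(f)[1]), log(mean(y)), tolerance = 1e-8)
  # score-equation property: average predicted mean equals ybar
  expect_equal(mean(predict(f)), mean(y), tolerance = 1e-8)
})

test_that("poisson fit matches glm (independent cross-check)", {
  s <- sim_xy(300, c(1, 0.5, -0.3), "poisson", seed = 21)
  f <- fit_count_model(s$X, s$y, family = "poisson")
  g <- glm(s$y ~ s$X - 1, family = poisson())
  expect_true(f$converged)
  expect_equal(unname(coef(f)), unname(coef(g)), tolerance = 1e-6)
  expect_equal(unname(f$std_errors),
               unname(sqrt(diag(vcov(g)))), tolerance = 1e-4)
  # Poisson score identity at the MLE
  expect_lt(abs(sum(s$y - predict(f))), 1e-6 * length(s$y))
})

test_that("gp fit recovers known parameters within 3 SEs", {
  s <- sim_xy(2000, c(1.0, 0.5), "gp", disp = 2, seed = 31)
  f <- fit_count_model(s$X, s$y, family = "gp")
  expect_true(f$converged)
  est <- coef(f)
  se <- f$std_errors
  truth <- c(1.0, 0.5, log(2))
  expect_true(all(abs(est - truth) <= 3 * se))
  expect_lt(abs(f$dispersion - 2), 3 * f$dispersion * se[3])
})

test_that("gp fit on equi-dispersed Poisson data estimates theta near 1", {
  s <- sim_xy(5000, c(1.2, 0.4), "poisson", seed = 41)
  f <- fit_count_model(s$X, s$y, family = "gp")
  expect_true(f$converged)
  expect_gte(f$dispersion, 0.9)
  expect_lte(f$dispersion, 1.1)
})

test_that("nb fit recovers known parameters", {
  s <- sim_xy(2000, c(1.0, 0.5), "nb", disp = 1.5, seed = 51)
  f <- fit_count_model(s$X, s$y, family = "nb")
  expect_true(f$converged)
  expect_true(all(abs(coef(f) - c(1.0, 0.5, log(1.5))) <= 3 * f$std_errors))
})

test_that("richer families never lose log-likelihood to Poisson (nesting)", {
  for (seed in c(1, 2, 3)) {
    s <- sim_xy(400, c(1, 0.3), "gp", disp = 1.8, seed = seed)
    fp <- fit_count_model(s$X, s$y, family = "poisson")
    fg <- fit_count_model(s$X, s$y, family = "gp")
    fn <- fit_count_model(s$X, s$y, family = "nb")
    expect_gte(fg$loglik, fp$loglik - 1e-6)
    expect_gte(fn$loglik, fp$loglik - 1e-6)
  }
})

test_that("wald table reproduces printed z and p arithmetic", {
  # z = estimate / SE, p two-sided normal: anchors from the published table
  expect_equal(0.0616 / 0.0241, 2.556, tolerance = 1e-3)
  s <- sim_xy(500, c(1, 0.5), "poisson", seed = 61)
  f <- fit_count_model(s$X, s$y, family = "poisson")
  w <- wald_inference(f)
  expect_equal(w$z, w$estimate / w$std_error)
  expect_equal(w$p_value, 2 * pnorm(-abs(w$z)))
  expect_true(all(w$p_value >= 0 & w$p_value <= 1))
  z <- -0.1507 / 0.0306
  expect_equal(z, -4.925, tolerance = 1e-3)
  expect_equal(2 * pnorm(-abs(z)), 8.44e-7, tolerance = 1e-2)
})

test_that("prediction follows the published GP equation arithmetic", {
  # hand-built fit carrying the published GP coefficient vector
  beta <- c(3.5400, 0.0616, 0.2264, -0.1507, 0.0132, -0.0017, 1.1720,
            -0.8480, -0.6483, -0.7265, -0.8064, -0.7467, -0.3392)
  X0 <- matrix(0, 2, 13)
  X0[, 1] <- 1          # intercept
  X0[2, 7] <- 1         # switch the urban dummy on
  cols <- c("(Intercept)", paste0("b", 2:13))
  colnames(X0) <- cols
  fake <- structure(list(coefficients = setNames(beta, cols), X = X0),
                    class = "countdisp_fit")
  mu <- predict(fake, X0)
  expect_equal(mu[1], exp(3.540), tolerance = 1e-10)   # ~34.47
  expect_equal(mu[2] / mu[1], exp(1.172), tolerance = 1e-10)
  expect_true(all(mu > 0))
  # column mismatch is a schema error
  bad <- X0[, c(2, 1, 3:13)]
  expect_error(predict(fake, bad), "columns")
})

test_that("95% Wald intervals attain nominal coverage under each family", {
  n_rep <- 60
  beta <- c(1.0, 0.5)
  for (fam in c("poisson", "gp")) {
    hits <- 0L
    total <- 0L
    for (rep in seq_len(n_rep)) {
      s <- sim_xy(500, beta, fam, disp = if (fam == "gp") 2 else NULL,
                  seed = 7000 + rep)
      f <- fit_count_model(s$X, s$y, family = fam)
      if (!f$converged) next
      ci_lo <- coef(f)[1:2] - 1.96 * f$std_errors[1:2]
      ci_hi <- coef(f)[1:2] + 1.96 * f$std_errors[1:2]
      hits <- hits + sum(beta >= ci_lo & beta <= ci_hi)
      total <- total + 2L
    }
    expect_gte(hits / total, 0.90)
    expect_lte(hits / total, 0.99)
  }
})

test_that("degenerate designs are refused", {
  X <- cbind(1, c(1, 2, 3, 4), c(2, 4, 6, 8))   # collinear
  expect_error(fit_count_model(X, c(1, 2, 1, 3), family = "poisson"),
               "rank")
  expect_error(fit_count_model(matrix(1, 3, 1), c(1, -2, 1), family = "poisson"),
               "non-negative")
})
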
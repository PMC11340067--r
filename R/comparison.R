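#' Information criteria for a fitted model
#'
#' Standard definitions on the maximized log-likelihood \eqn{\ell}:
#' \eqn{AIC = -2\ell + 2k}, \eqn{AICc = AIC + 2k(k+1)/(n-k-1)},
#' \eqn{BIC = -2\ell + k\ln n}, with `k` counting every estimated
#' parameter (regression coefficients plus any dispersion parameter) and
#' `n` the effective sample size.  `n` is passed explicitly rather than
#' taken from a fit so published tables with a stated effective n can be
#' reproduced directly.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters.
#' @param n effective sample size; must exceed `k + 1` for AICc.
#' @return a list with `aic`, `aicc`, `bic`.
#' @examples
#' information_criteria(-914.617, k = 14, n = 177)
#' @export
information_criteria <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined: need n > k + 1", call. = FALSE)
  aic <- -2 * loglik + 2 * k
  list(
    aic = aic,
    aicc = aic + 2 * k * (k + 1) / (n - k - 1),
    bic = -2 * loglik + k * log(n)
  )
}

#' Pearson chi-square dispersion diagnostic
#'
#' \eqn{\chi^2 = \sum_i (y_i - \hat\mu_i)^2 / \widehat{V}(y_i)} with the
#' fitted family's variance function (Poisson \eqn{\hat\mu}; NB
#' \eqn{\hat\mu + \hat\mu^2/\hat\alpha}; GP \eqn{\hat\vartheta^2\hat\mu}),
#' over residual degrees of freedom \eqn{df = n_{used} - k}.  A ratio
#' well above one under the Poisson fit signals over-dispersion; a ratio
#' near one indicates the dispersion is adequately modelled.
#'
#' @param fit a `"countdisp_fit"`.
#' @param X,y optional data overriding the fit's stored training data.
#' @return a list with `chi2`, `df`, `ratio`.
#' @export
pearson_chi2 <- function(fit, X = NULL, y = NULL) {
  stopifnot(inherits(fit, "countdisp_fit"))
  if (inherits(X, "council_design")) { y <- X$y; X <- X$X }
  X <- X %||% fit$X
  y <- y %||% fit$y
  mu <- predict(fit, X)
  v <- family_variance(fit$family, mu, fit$dispersion)
  df <- length(y) - fit$k_params
  if (df <= 0) stop("non-positive residual degrees of freedom", call. = FALSE)
  chi2 <- sum((y - mu)^2 / v)
  list(chi2 = chi2, df = df, ratio = chi2 / df)
}

#' Model-adequacy comparison table
#'
#' One row per fitted model with \eqn{-2\ell}, AIC, AICc, BIC, the Pearson
#' chi-square, its degrees of freedom and the dispersion ratio, sorted
#' ascending by AIC (ties broken by BIC, then model name).
#'
#' @param fits a list of `"countdisp_fit"` objects sharing the same data.
#' @param n effective sample size used in the criteria; defaults to the
#'   common `n_used` of the fits.
#' @return a data frame of class `"comparison_table"` with columns
#'   `model`, `loglik`, `minus2loglik`, `aic`, `aicc`, `bic`,
#'   `pearson_chi2`, `df`, `pearson_ratio`, `n`, `k`.
#' @export
comparison_table <- function(fits, n = NULL) {
  if (inherits(fits, "countdisp_fit")) fits <- list(fits)
  if (length(fits) == 0L) stop("`fits` is empty", call. = FALSE)
  ns <- vapply(fits, function(f) f$n_used, 0)
  if (length(unique(ns)) != 1L) {
    stop("fits were made on different effective sample sizes", call. = FALSE)
  }
  n <- n %||% ns[1]
  rows <- lapply(fits, function(f) {
    ic <- information_criteria(f$loglik, f$k_params, n)
    pc <- pearson_chi2(f)
    data.frame(
      model = f$family, loglik = f$loglik, minus2loglik = -2 * f$loglik,
      aic = ic$aic, aicc = ic$aicc, bic = ic$bic,
      pearson_chi2 = pc$chi2, df = pc$df, pearson_ratio = pc$ratio,
      n = n, k = f$k_params
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$aic, out$bic, out$model), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' @export
print.comparison_table <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], round, digits)
  print(y, row.names = FALSE)
  invisible(x)
}
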
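#' Maximum-likelihood Gamma fit
#'
#' Fits a two-parameter Gamma distribution (location fixed at zero) by
#' maximum likelihood. Reliability, response-size and overlap distributions
#' of third-order olfactory neurons are all well described by low-shape
#' Gammas, so the fitted (shape, scale) pair is the standard summary of a
#' response-property distribution here.
#'
#' @param values positive numeric vector, length >= 10.
#' @return An object of class `gamma_fit`: `shape`, `scale`, `rate`,
#'   standard errors, log-likelihood, `n`, and the Kolmogorov-Smirnov
#'   distance to the fitted distribution as `goodness`.
#' @seealso [cumulative_frequency()] for the nonparametric plotting curve.
#' @export
fit_gamma <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 10) stop("need at least 10 values")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("all values must be positive and finite")
  if (stats::sd(values) == 0) stop("degenerate input: all values identical")
  fit <- suppressWarnings(MASS::fitdistr(values, "gamma"))
  shape <- unname(fit$estimate["shape"])
  rate <- unname(fit$estimate["rate"])
  ks <- suppressWarnings(
    stats::ks.test(values, "pgamma", shape = shape, rate = rate)$statistic)
  structure(list(shape = shape, scale = 1 / rate, rate = rate,
                 se = fit$sd, loglik = fit$loglik, n = length(values),
                 method = "mle", goodness = unname(ks)),
            class = "gamma_fit")
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat(sprintf("<gamma_fit> shape = %.4g, scale = %.4g (n = %d, KS = %.3g)\n",
              x$shape, x$scale, x$n, x$goodness))
  invisible(x)
}

#' @export
coef.gamma_fit <- function(object, ...) {
  c(shape = object$shape, scale = object$scale)
}

#' Nonparametric cumulative frequency curve
#'
#' Sorts the values and assigns each the fraction of observations at or
#' below it -- the distribution-free way of plotting a frequency histogram
#' used for the reliability/response/overlap curves.
#'
#' @param values numeric vector.
#' @return A data frame with columns `value` and `cum_freq`, one row per
#'   distinct value.
#' @export
cumulative_frequency <- function(values) {
  v <- sort(values)
  u <- unique(v)
  data.frame(value = u,
             cum_freq = vapply(u, function(x) mean(v <= x), 0))
}
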
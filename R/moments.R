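#' Beta distribution from a mean and standard error
#'
#' Method-of-moments conversion of a (mean, SE) pair into the shape
#' parameters of a Beta distribution with exactly that mean and variance,
#' the standard construction for probabilistic sensitivity analysis of
#' probability and utility parameters.
#'
#' @param mean Mean of the target distribution, strictly between 0 and 1.
#' @param se Standard error (standard deviation of the target distribution),
#'   positive.  Must satisfy `se^2 < mean * (1 - mean)`, the Bernoulli
#'   variance bound; outside it no Beta distribution has these moments.
#' @param name Optional parameter name used in error messages.
#' @return A list with components `alpha` and `beta`, both positive.
#' @examples
#' beta_from_moments(0.20, 0.03)   # MSE sensitivity
#' beta_from_moments(0.5, sqrt(1 / 12))  # the uniform distribution
#' @export
beta_from_moments <- function(mean, se, name = NULL) {
  who <- if (is.null(name)) "parameter" else sprintf("parameter '%s'", name)
  if (!is.finite(mean) || mean <= 0 || mean >= 1) {
    stop(sprintf("%s: beta mean must lie strictly in (0, 1), got %g", who, mean))
  }
  if (!is.finite(se) || se <= 0) {
    stop(sprintf("%s: se must be positive, got %g", who, se))
  }
  v <- se^2
  if (v >= mean * (1 - mean)) {
    stop(sprintf(
      "%s: moment matching infeasible, se^2 = %g >= mean*(1-mean) = %g",
      who, v, mean * (1 - mean)
    ))
  }
  nu <- mean * (1 - mean) / v - 1
  list(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Gamma distribution from a mean and standard error
#'
#' Method-of-moments conversion of a (mean, SE) pair into shape/scale
#' parameters of a Gamma distribution, used for cost parameters.
#'
#' @param mean Mean of the target distribution, positive (e.g. THB).
#' @param se Standard error, positive.
#' @param name Optional parameter name used in error messages.
#' @return A list with components `shape` (`mean^2/se^2`) and `scale`
#'   (`se^2/mean`).
#' @examples
#' gamma_from_moments(758, 177)   # precancer treatment cost
#' gamma_from_moments(100, 100)   # the exponential case: shape 1
#' @export
gamma_from_moments <- function(mean, se, name = NULL) {
  who <- if (is.null(name)) "parameter" else sprintf("parameter '%s'", name)
  if (!is.finite(mean) || mean <= 0) {
    stop(sprintf("%s: gamma mean must be positive, got %g", who, mean))
  }
  if (!is.finite(se) || se <= 0) {
    stop(sprintf("%s: se must be positive, got %g", who, se))
  }
  list(shape = mean^2 / se^2, scale = se^2 / mean)
}

#' Confidence bounds of a distributed parameter
#'
#' Quantiles of the moment-matched sampling distribution of a parameter,
#' used as the low/high range of one-way sensitivity analyses.
#'
#' @param p A single-parameter record: a list or one-row data frame with
#'   fields `mean`, `se` and `family` (one of `"beta"`, `"gamma"`).
#' @param level Central coverage of the interval (default 0.95, i.e. the
#'   2.5th and 97.5th percentiles).
#' @return Numeric vector `c(low, high)` with `low < mean < high`.
#' @export
confidence_bounds <- function(p, level = 0.95) {
  p <- as.list(p)
  name <- if (!is.null(p$name)) p$name else "parameter"
  if (is.null(p$family) || identical(p$family, "fixed")) {
    stop(sprintf("'%s' is a fixed parameter and is not varied", name))
  }
  if (is.null(p$se) || is.na(p$se)) {
    stop(sprintf("'%s' has no standard error", name))
  }
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    stop("level must lie strictly in (0, 1)")
  }
  pr <- c((1 - level) / 2, 1 - (1 - level) / 2)
  out <- switch(p$family,
    beta = {
      sh <- beta_from_moments(p$mean, p$se, name)
      stats::qbeta(pr, sh$alpha, sh$beta)
    },
    gamma = {
      sh <- gamma_from_moments(p$mean, p$se, name)
      stats::qgamma(pr, shape = sh$shape, scale = sh$scale)
    },
    stop(sprintf("'%s': unknown distribution family '%s'", name, p$family))
  )
  names(out) <- c("low", "high")
  out
}

# Draw n values from the moment-matched distribution of one parameter record.
sample_parameter <- function(p, n = 1) {
  p <- as.list(p)
  switch(p$family,
    beta = {
      sh <- beta_from_moments(p$mean, p$se, p$name)
      stats::rbeta(n, sh$alpha, sh$beta)
    },
    gamma = {
      sh <- gamma_from_moments(p$mean, p$se, p$name)
      stats::rgamma(n, shape = sh$shape, scale = sh$scale)
    },
    stop(sprintf("cannot sample fixed parameter '%s'", p$name))
  )
}
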
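#' Lognormal log-density
#'
#' Standard lognormal log-density with location `mu` and scale `sigma` of the
#' underlying normal.  Values outside the support return `-Inf` (not an
#' error) so MCMC proposals can be rejected cleanly.
#'
#' @param x Evaluation point(s).
#' @param mu,sigma Location and scale of the underlying normal (`sigma > 0`).
#' @return Log-density; `-Inf` for `x <= 0`.
#' @export
lognormal_logpdf <- function(x, mu, sigma) {
  stopifnot(sigma > 0)
  out <- rep(-Inf, length(x))
  ok <- is.finite(x) & x > 0
  out[ok] <- dlnorm(x[ok], meanlog = mu, sdlog = sigma, log = TRUE)
  out
}

# log integrand of the continuous Poisson: c*log(lambda) - lambda - lgamma(c+1)
cpois_logf <- function(c, lambda) c * log(lambda) - lambda - lgamma(c + 1)

# log normalizer log R(lambda), R = integral over c in (0, Inf), by adaptive
# quadrature with a log-scale shift at the integrand's mode (c* ~ lambda).
lnR_direct <- function(lambda) {
  cstar <- max(lambda - 0.5, 1e-3)
  lmax <- cpois_logf(cstar, lambda)
  f <- function(c) exp(cpois_logf(c, lambda) - lmax)
  # split at the mode so adaptive quadrature cannot miss a peak far from 0
  val <- integrate(f, 0, cstar, rel.tol = 1e-10, abs.tol = 0)$value +
    integrate(f, cstar, Inf, rel.tol = 1e-10, abs.tol = 0)$value
  lmax + log(val)
}

# lambda-grid spline cache for log R(lambda); direct quadrature outside the
# grid.  Grid error vs direct quadrature < 1e-6 (tested).
.lnR_cache <- new.env(parent = emptyenv())

lnR <- function(lambda) {
  if (lambda < 0.05 || lambda > 500) return(lnR_direct(lambda))
  if (is.null(.lnR_cache$fun)) {
    grid <- exp(seq(log(0.05), log(500), length.out = 600))
    vals <- vapply(grid, lnR_direct, numeric(1))
    .lnR_cache$fun <- splinefun(log(grid), vals, method = "natural")
  }
  .lnR_cache$fun(log(lambda))
}

#' Zero-truncated continuous Poisson log-density
#'
#' Poisson-shaped density on positive reals, with the factorial replaced by a
#' gamma function and renormalized to exclude zero:
#' `log(lambda^c exp(-lambda) / Gamma(c + 1)) - log R(lambda)` with
#' `R(lambda) = integral_0^Inf lambda^c exp(-lambda) / Gamma(c + 1) dc`.
#' The normalizer is computed by adaptive quadrature and cached on a
#' lambda grid with spline interpolation (recomputed exactly off-grid).
#' Models unobserved plasmid copy number, whose magnitude is confounded with
#' the transcription rate and therefore treated as continuous.
#'
#' @param c Copy number value(s) (> 0; `-Inf` returned otherwise).
#' @param lambda Poisson rate (> 0).
#' @return Log-density values.
#' @export
trunc_cpoisson_logpdf <- function(c, lambda) {
  stopifnot(length(lambda) == 1, is.finite(lambda), lambda > 0)
  out <- rep(-Inf, length(c))
  ok <- is.finite(c) & c > 0
  out[ok] <- cpois_logf(c[ok], lambda) - lnR(lambda)
  out
}

#' Gamma log-density for the measurement precision
#'
#' The measurement error variance has a gamma prior on the precision
#' `1/sigma_eps2`.  With `var_param = FALSE` this is the gamma log-density at
#' `prec`; with `var_param = TRUE` the argument is interpreted as
#' `sigma_eps2` itself and the change-of-variable Jacobian
#' `|d prec / d sigma_eps2| = sigma_eps2^-2` is included, giving the density
#' over the variance.  (MCMC proposals act on `log sigma_eps2`; that Jacobian
#' is applied separately in the acceptance ratio.)
#'
#' @param x Precision (default) or variance (`var_param = TRUE`); > 0.
#' @param shape,rate Gamma parameters (> 0).
#' @param var_param Interpret `x` as the variance and add the Jacobian.
#' @return Log-density; `-Inf` outside the support.
#' @export
gamma_precision_logpdf <- function(x, shape, rate, var_param = FALSE) {
  stopifnot(shape > 0, rate > 0)
  out <- rep(-Inf, length(x))
  ok <- is.finite(x) & x > 0
  if (var_param) {
    out[ok] <- dgamma(1 / x[ok], shape = shape, rate = rate, log = TRUE) -
      2 * log(x[ok])
  } else {
    out[ok] <- dgamma(x[ok], shape = shape, rate = rate, log = TRUE)
  }
  out
}

#' Hyperparameters of the population layer
#'
#' Parameters of the hierarchical distributions: per-group lognormal
#' location/scale for the on- and off-phase transcription rates, a global
#' lognormal for the translation rate, gamma shape/rate over the measurement
#' precision, and the rate of the zero-truncated continuous Poisson copy
#' number distribution (shared across all groups, which is what makes
#' between-group rate ratios comparable).
#'
#' @param groups Character vector of group labels.
#' @param mu_tau_on,sigma_tau_on Named per-group location/scale of the
#'   on-rate lognormal.
#' @param mu_tau_off,sigma_tau_off Per-group (named) or global (scalar)
#'   location/scale of the off-rate lognormal.
#' @param mu_alpha,sigma_alpha Global translation-rate lognormal parameters.
#' @param precision_shape,precision_rate Gamma parameters over `1/sigma_eps2`.
#' @param copy_lambda Rate of the truncated continuous Poisson.
#' @return An object of class `hyperparams`.
#' @export
hyperparams <- function(groups, mu_tau_on, sigma_tau_on,
                        mu_tau_off, sigma_tau_off,
                        mu_alpha, sigma_alpha,
                        precision_shape, precision_rate, copy_lambda) {
  stopifnot(
    setequal(names(mu_tau_on), groups), setequal(names(sigma_tau_on), groups),
    all(sigma_tau_on > 0), all(sigma_tau_off > 0), sigma_alpha > 0,
    precision_shape > 0, precision_rate > 0, copy_lambda > 0,
    length(mu_tau_off) %in% c(1, length(groups)),
    length(mu_tau_off) == length(sigma_tau_off)
  )
  if (length(mu_tau_off) > 1) {
    stopifnot(setequal(names(mu_tau_off), groups))
  }
  structure(
    list(groups = groups,
         mu_tau_on = mu_tau_on[groups], sigma_tau_on = sigma_tau_on[groups],
         mu_tau_off = mu_tau_off, sigma_tau_off = sigma_tau_off,
         mu_alpha = mu_alpha, sigma_alpha = sigma_alpha,
         precision_shape = precision_shape, precision_rate = precision_rate,
         copy_lambda = copy_lambda),
    class = "hyperparams"
  )
}

# Per-group lookup that transparently supports a global (length-1) tau_off.
psi_tau_off <- function(psi, group) {
  if (length(psi$mu_tau_off) == 1) {
    c(psi$mu_tau_off[[1]], psi$sigma_tau_off[[1]])
  } else {
    c(psi$mu_tau_off[[group]], psi$sigma_tau_off[[group]])
  }
}

#' Log prior density of one cell's parameters given the population layer
#'
#' Sum of: lognormal terms for `tau_on`, `tau_off` (group-specific) and
#' `alpha` (global); the gamma-precision term for `sigma_eps2` (density over
#' the variance); the truncated continuous Poisson term for `copy_number`;
#' and a flat prior for `switch_time` over the observation window.  The
#' fixed constants `delta_M`, `delta_P`, `kappa` contribute nothing.
#'
#' @param theta One-row tibble (or named list) with `tau_on`, `tau_off`,
#'   `switch_time`, `alpha`, `copy_number`, `sigma_eps2`.
#' @param psi A [hyperparams()].
#' @param group Group label of the cell.
#' @param t_window Length-2 observation window for the switch-time prior.
#' @return Log prior density; `-Inf` out of support.
#' @export
log_prior_cell <- function(theta, psi, group, t_window) {
  stopifnot(inherits(psi, "hyperparams"), group %in% psi$groups)
  toff <- psi_tau_off(psi, group)
  s_ok <- is.finite(theta$switch_time) &&
    theta$switch_time >= t_window[1] && theta$switch_time <= t_window[2]
  lognormal_logpdf(theta$tau_on, psi$mu_tau_on[[group]],
                   psi$sigma_tau_on[[group]]) +
    lognormal_logpdf(theta$tau_off, toff[1], toff[2]) +
    lognormal_logpdf(theta$alpha, psi$mu_alpha, psi$sigma_alpha) +
    gamma_precision_logpdf(theta$sigma_eps2, psi$precision_shape,
                           psi$precision_rate, var_param = TRUE) +
    trunc_cpoisson_logpdf(theta$copy_number, psi$copy_lambda) +
    (if (s_ok) -log(t_window[2] - t_window[1]) else -Inf)
}

#' Log hyperprior over the population-layer parameters
#'
#' Weakly informative, proper forms: normal(0, 10^2) on every lognormal
#' location, half-normal(scale 5) on every lognormal scale,
#' exponential(rate 0.01) on the (dimensionless) precision shape and on the
#' copy lambda, and lognormal(0, 10) on the precision rate.  The precision
#' rate carries the units of the measurement precision, so its hyperprior
#' must be diffuse across *scales* — an exponential there would tie the
#' analysis to the absolute signal scale and break the invariance of rate
#' ratios under global signal rescaling.
#'
#' @param psi A [hyperparams()].
#' @return Log hyperprior density; `-Inf` out of support.
#' @export
log_hyperprior <- function(psi) {
  stopifnot(inherits(psi, "hyperparams"))
  half_normal <- function(x, scale) {
    ifelse(is.finite(x) & x > 0, log(2) + dnorm(x, 0, scale, log = TRUE), -Inf)
  }
  expo <- function(x, rate) {
    ifelse(is.finite(x) & x > 0, dexp(x, rate, log = TRUE), -Inf)
  }
  mus <- c(psi$mu_tau_on, psi$mu_tau_off, psi$mu_alpha)
  sigmas <- c(psi$sigma_tau_on, psi$sigma_tau_off, psi$sigma_alpha)
  rate_term <- if (is.finite(psi$precision_rate) && psi$precision_rate > 0) {
    dlnorm(psi$precision_rate, 0, 10, log = TRUE)
  } else {
    -Inf
  }
  sum(dnorm(mus, 0, 10, log = TRUE)) +
    sum(half_normal(sigmas, 5)) +
    expo(psi$precision_shape, 0.01) +
    rate_term +
    expo(psi$copy_lambda, 0.01)
}
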
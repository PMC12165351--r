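#' Student t density (closed form)
#'
#' Direct evaluation of the central t density
#' \deqn{t_\nu(x) = \frac{\Gamma((\nu+1)/2)}{\sqrt{\pi\nu}\,\Gamma(\nu/2)}
#'       \left(1 + x^2/\nu\right)^{-(\nu+1)/2}}
#' via log-gamma, the form the error model is written in. Agrees with
#' `stats::dt()` to machine precision; kept explicit so the cost-function
#' algebra is self-contained.
#'
#' @param x Evaluation point(s).
#' @param nu Degrees of freedom, > 0.
#' @return Density value(s), non-negative.
#' @examples
#' t_density(0, 1)  # Cauchy: 1/pi
#' @export
t_density <- function(x, nu) {
  stopifnot(all(nu > 0))
  exp(lgamma((nu + 1) / 2) - lgamma(nu / 2) - 0.5 * log(pi * nu) -
        ((nu + 1) / 2) * log1p(x^2 / nu))
}

#' Two-tailed type I error probability
#'
#' \eqn{\alpha(x) = 2 F_\nu(-|x|)}: the probability that a central t statistic
#' exceeds the critical value `x` in absolute value, i.e. the false-positive
#' rate of a two-tailed test that rejects when |t| > x.
#'
#' @param x Critical t value(s).
#' @param nu Degrees of freedom.
#' @return Probability in (0, 1].
#' @export
alpha_of_x <- function(x, nu) {
  2 * stats::pt(-abs(x), df = nu)
}

#' Two-tailed type II error probability
#'
#' \eqn{\beta(x) = F_\nu(|x|-\delta) - F_\nu(-|x|-\delta)}: the probability
#' that a t statistic shifted by the standardized minimum effect `delta`
#' falls inside the acceptance region (-x, x). This is the shifted-central-t
#' power model; see [likelihood_ratio()] for the noncentral alternative.
#'
#' @param x Critical t value(s).
#' @param nu Degrees of freedom.
#' @param delta Standardized shift, >= 0 (minimum effect size on the
#'   t-statistic scale).
#' @return Probability in \[0, 1\].
#' @export
beta_of_x <- function(x, nu, delta) {
  stopifnot(all(delta >= 0))
  stats::pt(abs(x) - delta, df = nu) - stats::pt(-abs(x) - delta, df = nu)
}

#' Error rates and weighted error at a critical value
#'
#' Evaluates the cost function
#' \deqn{\varepsilon(x) = C \cdot pr \cdot \beta(x) + (1 - pr)\,\alpha(x),}
#' the weighted sum of type II and type I error probabilities, where `C` is
#' the seriousness of a type II error relative to a type I error and `pr`
#' the prior probability that the alternative hypothesis is true.
#'
#' @param x Critical t value(s).
#' @param nu Degrees of freedom.
#' @param delta Standardized minimum effect shift.
#' @param prior Prior probability of H1, in (0, 1).
#' @param c_ratio Relative seriousness of type II error, > 0.
#' @return A tibble with columns `x`, `alpha`, `beta`, `epsilon` (one row per
#'   element of `x`).
#' @examples
#' error_rates(1.96, nu = 98, delta = 2.5)
#' @export
error_rates <- function(x, nu, delta, prior = 0.5, c_ratio = 0.25) {
  check_weights(prior, c_ratio)
  a <- alpha_of_x(x, nu)
  b <- beta_of_x(x, nu, delta)
  tibble::tibble(x = x, alpha = a, beta = b,
                 epsilon = c_ratio * prior * b + (1 - prior) * a)
}

# plain-numeric epsilon, used in the solver's hot path
weighted_error_at <- function(x, nu, delta, prior, c_ratio) {
  c_ratio * prior * beta_of_x(x, nu, delta) +
    (1 - prior) * alpha_of_x(x, nu)
}

#' Stationarity residual of the weighted error cost
#'
#' Setting the derivative of the weighted error to zero gives the
#' transcendental equation
#' \deqn{\frac{t_\nu(|x|)}{t_\nu(|x|-\delta) + t_\nu(|x|+\delta)} =
#'       \frac{C\,pr}{2(1-pr)} = k.}
#' This function returns the left-hand side minus `k`. The density ratio is
#' evaluated in log space so it stays finite far in the tails at large
#' degrees of freedom; the normalizing constants of the density cancel, so
#' this is identical to the raw power-form of the equation.
#'
#' @param x Candidate critical value(s); the residual is even in `x`.
#' @param nu Degrees of freedom.
#' @param delta Standardized minimum effect shift.
#' @param k Stationarity constant `c_ratio * prior / (2 * (1 - prior))`.
#' @return Residual value(s); a zero crossing on x > 0 is a stationary point
#'   of the weighted error.
#' @export
stationarity_residual <- function(x, nu, delta, k) {
  x  <- abs(x)
  l0 <- stats::dt(x, df = nu, log = TRUE)
  lm <- stats::dt(x - delta, df = nu, log = TRUE)
  lp <- stats::dt(x + delta, df = nu, log = TRUE)
  1 / (exp(lm - l0) + exp(lp - l0)) - k
}

#' Test geometry from two-arm summaries
#'
#' Reduces a two-arm trial plus decision weights to the three quantities the
#' threshold solver needs: the Welch--Satterthwaite degrees of freedom `nu`,
#' the minimum effect of interest on the t-statistic scale
#' \deqn{\delta = d \cdot s_1 / se_\Delta}
#' (anchored to the placebo-arm SD), and the stationarity constant
#' `k = c_ratio * prior / (2 (1 - prior))`.
#'
#' @param arms Two-arm summary table, see [arm_summaries()].
#' @param effect_size Minimum effect size of interest `d`, in placebo-SD
#'   units (Cohen's d convention; 0.5 is a medium effect).
#' @param prior Prior probability of H1.
#' @param c_ratio Relative seriousness of type II error.
#' @return A one-row tibble with columns `nu`, `delta`, `k`, `prior`,
#'   `c_ratio`, `effect_size`.
#' @examples
#' arm_summaries(50, 11.1, 2.0, 50, 13.4, 4.3) |> test_geometry()
#' @export
test_geometry <- function(arms, effect_size = 0.5, prior = 0.5, c_ratio = 0.25) {
  arms <- validate_arms(arms)
  check_weights(prior, c_ratio, effect_size)
  ws <- welch_stats(arms$n[1], arms$mean[1], arms$sd[1],
                    arms$n[2], arms$mean[2], arms$sd[2])
  tibble::tibble(
    nu = ws$nu,
    delta = effect_size * arms$sd[1] / ws$se_delta,
    k = stationarity_k(prior, c_ratio),
    prior = prior, c_ratio = c_ratio, effect_size = effect_size
  )
}

#' Test geometry assuming equal variances
#'
#' The a-priori geometry available before any data are seen: with equal
#' per-arm size `n` and equal variances, `nu = 2n - 2` and
#' `delta = d * sqrt(n / 2)`. Coincides with [test_geometry()] whenever the
#' measured per-arm SDs are equal.
#'
#' @param n Per-arm sample size, >= 2.
#' @inheritParams test_geometry
#' @return A one-row tibble with the same columns as [test_geometry()].
#' @examples
#' equal_variance_geometry(50)
#' @export
equal_variance_geometry <- function(n, effect_size = 0.5, prior = 0.5, c_ratio = 0.25) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 2 || n != round(n)) {
    rlang::abort("`n` must be a single integer >= 2")
  }
  check_weights(prior, c_ratio, effect_size)
  tibble::tibble(
    nu = 2 * n - 2,
    delta = effect_size * sqrt(n / 2),
    k = stationarity_k(prior, c_ratio),
    prior = prior, c_ratio = c_ratio, effect_size = effect_size
  )
}

stationarity_k <- function(prior, c_ratio) {
  c_ratio * prior / (2 * (1 - prior))
}

check_weights <- function(prior, c_ratio, effect_size = NULL) {
  if (!is.numeric(prior) || prior <= 0 || prior >= 1) {
    rlang::abort("`prior` must lie strictly between 0 and 1")
  }
  if (!is.numeric(c_ratio) || c_ratio <= 0) {
    rlang::abort("`c_ratio` must be a positive number")
  }
  if (!is.null(effect_size) && (!is.numeric(effect_size) || effect_size < 0)) {
    rlang::abort("`effect_size` must be non-negative")
  }
  invisible(TRUE)
}
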
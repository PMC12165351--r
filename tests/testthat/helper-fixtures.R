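# Shared fixtures: the two worked-example replicas and random-geometry draws.

replica1_arms <- function() arm_summaries(50, 11.1, 2.0, 50, 13.4, 4.3)
replica2_arms <- function() arm_summaries(50, 11.0, 1.8, 50, 12.4, 4.4)

# Draw a random geometry/weights tuple on which a stationary point exists,
# i.e. k below the supremum of the density ratio (the solver's precondition).
random_valid_geometry <- function() {
  repeat {
    nu <- runif(1, 3, 500)
    delta <- runif(1, 0.5, 6)
    prior <- runif(1, 0.1, 0.9)
    c_ratio <- runif(1, 0.1, 2)
    k <- c_ratio * prior / (2 * (1 - prior))
    xs <- seq(1e-3, delta + 12, length.out = 400)
    if (max(stationarity_residual(xs, nu, delta, k)) > 0 &&
        stationarity_residual(delta + 12, nu, delta, k) < 0) {
      return(list(nu = nu, delta = delta, prior = prior,
                  c_ratio = c_ratio, k = k))
    }
  }
}

# Independent power-form evaluation of the stationarity left-hand side,
# written directly from the unnormalized t-density kernels (the normalizing
# constants cancel in the ratio).
power_form_ratio <- function(x, nu, delta) {
  kern <- function(u) (1 + u^2 / nu)^(-(nu + 1) / 2)
  x <- abs(x)
  kern(x) / (kern(x - delta) + kern(x + delta))
}

# Plain bisection root finder used as an independent oracle for the solver.
bisect_root <- function(f, lo, hi, iter = 200) {
  flo <- f(lo)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (sign(fm) == sign(flo)) {
      lo <- mid
      flo <- fm
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}
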
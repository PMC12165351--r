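#' Solve for the flexible p-value significance threshold
#'
#' Finds the critical t value `x*` at which the weighted error
#' \eqn{\varepsilon(x) = C\,pr\,\beta(x) + (1-pr)\,\alpha(x)} is minimized,
#' by locating the zero of the stationarity residual
#' (see [stationarity_residual()]) on x > 0, and reports the flexible
#' p-value significance threshold `pst = alpha_of_x(x*, nu)`.
#'
#' The residual is scanned on a coarse log-linear grid over
#' `[1e-3, delta + 12]`; each sign change is refined with a bracketed root
#' finder (`stats::uniroot`, x tolerance 1e-10). When several stationary
#' points exist, the one with the smallest weighted error is kept, and a
#' local-minimum check against `x* +/- 1e-3` is enforced. If no bracket is
#' found, the solver falls back to bounded minimization of the weighted error
#' (`method = "fallback_minimize"`). `converged` is `TRUE` only when the
#' absolute residual at the solution is below 1e-8; with `delta = 0` and
#' `k != 1/2` no stationary point exists and the solver reports
#' `converged = FALSE` with `method = "none"`.
#'
#' @param geometry One-row (or multi-row) geometry table from
#'   [test_geometry()] or [equal_variance_geometry()]; columns `nu`, `delta`,
#'   `k`, `prior`, `c_ratio` are required.
#' @return The input tibble augmented with columns `x_crit`, `pst`, `alpha`,
#'   `beta`, `epsilon`, `residual`, `converged`, `method`; one row per
#'   geometry row.
#' @examples
#' equal_variance_geometry(50) |> solve_threshold()
#' @export
solve_threshold <- function(geometry) {
  need <- c("nu", "delta", "k", "prior", "c_ratio")
  if (!is.data.frame(geometry) || !all(need %in% names(geometry))) {
    rlang::abort("`geometry` must contain columns nu, delta, k, prior, c_ratio (see test_geometry())")
  }
  sols <- purrr::pmap(
    geometry[need],
    function(nu, delta, k, prior, c_ratio) {
      tibble::as_tibble(solve_pst_core(nu, delta, k, prior, c_ratio))
    }
  )
  dplyr::bind_cols(tibble::as_tibble(geometry), dplyr::bind_rows(sols))
}

# Core scalar solver. Returns a plain list (hot path of the simulator).
solve_pst_core <- function(nu, delta, k, prior, c_ratio, tol_res = 1e-8) {
  fail <- function(method) {
    list(x_crit = NA_real_, pst = NA_real_, alpha = NA_real_, beta = NA_real_,
         epsilon = NA_real_, residual = NA_real_, converged = FALSE,
         method = method)
  }
  if (delta <= 0) {
    # residual is identically 1/2 - k: no isolated stationary point
    return(fail("none"))
  }
  upper <- delta + 12
  f   <- function(x) stationarity_residual(x, nu, delta, k)
  eps <- function(x) weighted_error_at(x, nu, delta, prior, c_ratio)

  grid <- c(exp(seq(log(1e-3), 0, length.out = 12L)),
            seq(1.05, upper, length.out = 48L))
  fg <- f(grid)
  idx <- which(fg[-1] * fg[-length(fg)] < 0)

  roots <- vapply(idx, function(i) {
    r <- tryCatch(
      stats::uniroot(f, lower = grid[i], upper = grid[i + 1], tol = 1e-10),
      error = function(e) NULL
    )
    if (is.null(r)) NA_real_ else r$root
  }, numeric(1))
  roots <- roots[is.finite(roots)]

  x_crit <- NA_real_
  method <- "root"
  if (length(roots)) {
    # among stationary points keep the global epsilon minimizer that is a
    # genuine local minimum
    ev <- vapply(roots, eps, numeric(1))
    ord <- order(ev)
    for (j in ord) {
      x <- roots[j]
      h <- 1e-3
      if (ev[j] <= eps(max(x - h, 1e-8)) + 1e-12 && ev[j] <= eps(x + h) + 1e-12) {
        x_crit <- x
        break
      }
    }
  }
  if (!is.finite(x_crit)) {
    opt <- tryCatch(stats::optimize(eps, c(1e-6, upper), tol = 1e-10),
                    error = function(e) NULL)
    if (is.null(opt)) return(fail("fallback_minimize"))
    x_crit <- opt$minimum
    method <- "fallback_minimize"
  }

  res <- f(x_crit)
  list(
    x_crit = x_crit,
    pst = alpha_of_x(x_crit, nu),
    alpha = alpha_of_x(x_crit, nu),
    beta = beta_of_x(x_crit, nu, delta),
    epsilon = eps(x_crit),
    residual = res,
    converged = is.finite(res) && abs(res) <= tol_res,
    method = method
  )
}

#' Flexible PST for a two-arm trial
#'
#' End-to-end wrapper: builds the test geometry from the two-arm summaries
#' (measured per-arm SDs by default, or the equal-variance a-priori geometry)
#' and solves for the threshold. Returns a fitted-object wrapper with
#' [tidy()], [glance()], `print()` and [ggplot2::autoplot()] methods.
#'
#' @inheritParams test_geometry
#' @param equal_variances If `TRUE`, ignore the measured SDs and use the
#'   equal-variance geometry (`nu = 2n - 2`, `delta = d * sqrt(n/2)`); the
#'   per-arm sizes must then be equal.
#' @return An object of class `pst_solution`.
#' @examples
#' fit <- arm_summaries(50, 11.1, 2.0, 50, 13.4, 4.3) |> flexible_pst()
#' fit
#' tidy(fit)
#' @export
flexible_pst <- function(arms, effect_size = 0.5, prior = 0.5, c_ratio = 0.25,
                         equal_variances = FALSE) {
  arms <- validate_arms(arms)
  geom <- if (equal_variances) {
    if (arms$n[1] != arms$n[2]) {
      rlang::abort("equal-variance geometry assumes equal per-arm sample sizes")
    }
    equal_variance_geometry(arms$n[1], effect_size, prior, c_ratio)
  } else {
    test_geometry(arms, effect_size, prior, c_ratio)
  }
  sol <- solve_threshold(geom)
  structure(
    list(solution = sol, arms = arms, equal_variances = equal_variances),
    class = "pst_solution"
  )
}

#' @export
print.pst_solution <- function(x, ...) {
  s <- x$solution
  cat("Flexible p-value significance threshold\n")
  cat(sprintf("  geometry: nu = %.3f, delta = %.4f, k = %.4f%s\n",
              s$nu, s$delta, s$k,
              if (x$equal_variances) " (equal variances assumed)" else ""))
  if (isTRUE(s$converged) || is.finite(s$x_crit)) {
    cat(sprintf("  critical t  x* = %.4f\n", s$x_crit))
    cat(sprintf("  PST = %.3f   (alpha = %.4f, beta = %.4f, epsilon = %.4f)\n",
                s$pst, s$alpha, s$beta, s$epsilon))
    cat(sprintf("  converged: %s (%s)\n", s$converged, s$method))
  } else {
    cat("  no stationary point found (converged = FALSE)\n")
  }
  invisible(x)
}

#' @rdname flexible_pst
#' @param x A `pst_solution` object.
#' @param ... Unused.
#' @export
tidy.pst_solution <- function(x, ...) {
  dplyr::select(x$solution, "x_crit", "pst", "alpha", "beta", "epsilon")
}

#' @rdname flexible_pst
#' @export
glance.pst_solution <- function(x, ...) {
  dplyr::select(x$solution, "nu", "delta", "k", "residual", "converged", "method")
}

#' Weighted-error profile plot for a threshold solution
#'
#' Draws the weighted error curve \eqn{\varepsilon(x)} over the critical
#' value, with the type I and II components, and marks the solved minimum.
#'
#' @param object A `pst_solution` from [flexible_pst()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pst_solution <- function(object, ...) {
  s <- object$solution
  xs <- seq(1e-3, s$delta + 6, length.out = 400)
  df <- error_rates(xs, s$nu, s$delta, s$prior, s$c_ratio) |>
    dplyr::mutate(
      `type I  (1-pr) a` = (1 - s$prior) * .data$alpha,
      `type II C pr b`   = s$c_ratio * s$prior * .data$beta
    ) |>
    tidyr::pivot_longer(c("epsilon", "type I  (1-pr) a", "type II C pr b"),
                        names_to = "component", values_to = "value")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$value,
                                        colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "critical t value x", y = "weighted error",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (is.finite(s$x_crit)) {
    p <- p + ggplot2::geom_vline(xintercept = s$x_crit, linetype = "dashed")
  }
  p
}
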
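#' Configure a Monte Carlo trial simulation
#'
#' Describes a grid of two-arm Gaussian trial conditions. For every
#' combination of per-arm size and treatment-arm SD, the simulator draws
#' `n_reps` replicas with the null true (both arms mean 0) and `n_reps`
#' with the alternative true (treatment mean = `effect_size`), analyzes each
#' with Welch's t test, and judges significance under each requested
#' criterion. The placebo arm is always standard normal, so `sd_treatment`
#' is the SD ratio s2/s1 and `effect_size` is on the placebo-SD scale.
#'
#' The defaults are the study conditions of the reference analysis: medium
#' minimum effect size (0.5), prior probability of a real effect 0.5, and a
#' type II error a quarter as serious as a type I error (the conventional
#' alpha 0.05 / beta 0.2 trade-off).
#'
#' @param n_per_arm Integer vector of per-arm sample sizes.
#' @param sd_treatment Positive vector of treatment-arm SDs (placebo SD is 1).
#' @param effect_size Treatment mean under H1, in placebo-SD units.
#' @param prior Prior probability of H1, in (0, 1).
#' @param c_ratio Relative seriousness of type II error, > 0.
#' @param criteria Subset of `"fixed_0.05"`, `"fixed_0.005"`,
#'   `"flexible_equal"` (threshold from the a-priori equal-variance
#'   geometry), `"flexible_measured"` (threshold recomputed from each
#'   replica's own SDs).
#' @param n_reps Replicas per condition and hypothesis.
#' @param seed Master seed; every condition/hypothesis pair gets its own
#'   reproducible substream derived from it.
#' @return A `scenario_config` object (validated list).
#' @examples
#' scenario_config(n_per_arm = 50, sd_treatment = 1, n_reps = 100)
#' @export
scenario_config <- function(n_per_arm = c(50, 100, 200, 500, 1000),
                            sd_treatment = c(0.5, 1, 2),
                            effect_size = 0.5,
                            prior = 0.5,
                            c_ratio = 0.25,
                            criteria = c("fixed_0.05", "fixed_0.005",
                                         "flexible_equal", "flexible_measured"),
                            n_reps = 2000,
                            seed = 1L) {
  known <- c("fixed_0.05", "fixed_0.005", "flexible_equal", "flexible_measured")
  criteria <- as.character(criteria)
  if (length(criteria) == 0L || !all(criteria %in% known)) {
    rlang::abort(paste0("`criteria` must be a non-empty subset of: ",
                        paste(known, collapse = ", ")))
  }
  if (any(n_per_arm < 2) || any(n_per_arm != round(n_per_arm))) {
    rlang::abort("`n_per_arm` must be integers >= 2")
  }
  if (any(sd_treatment <= 0)) rlang::abort("`sd_treatment` must be positive")
  if (length(n_reps) != 1L || n_reps < 1 || n_reps != round(n_reps)) {
    rlang::abort("`n_reps` must be a positive integer")
  }
  if (length(seed) != 1L || !is.finite(seed)) rlang::abort("`seed` must be a single integer")
  check_weights(prior, c_ratio, effect_size)
  structure(
    list(n_per_arm = as.integer(n_per_arm),
         sd_treatment = as.numeric(sd_treatment),
         effect_size = effect_size, prior = prior, c_ratio = c_ratio,
         criteria = criteria, n_reps = as.integer(n_reps),
         seed = as.integer(seed)),
    class = "scenario_config"
  )
}

#' Read a simulation configuration from YAML or JSON
#'
#' @param path File whose extension is `.yaml`/`.yml` or `.json`; fields
#'   mirror the arguments of [scenario_config()], with unspecified fields
#'   taking the defaults.
#' @return A `scenario_config` object.
#' @export
read_scenario_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = ,
    yml  = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path),
    rlang::abort("config file must be .yaml, .yml, or .json")
  )
  do.call(scenario_config, cfg)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Trial simulation config\n")
  cat("  n per arm   :", paste(x$n_per_arm, collapse = ", "), "\n")
  cat("  sd treatment:", paste(x$sd_treatment, collapse = ", "), "\n")
  cat(sprintf("  effect size : %g   prior: %g   C: %g\n",
              x$effect_size, x$prior, x$c_ratio))
  cat("  criteria    :", paste(x$criteria, collapse = ", "), "\n")
  cat(sprintf("  n_reps      : %d   seed: %d\n", x$n_reps, x$seed))
  invisible(x)
}

# deterministic substream seed for condition index i and hypothesis
substream_seed <- function(seed, i, hypothesis) {
  h <- as.numeric(hypothesis == "H1")
  as.integer((abs(as.numeric(seed)) * 100003 + i * 2 + h) %% 2147483647)
}

# One simulated trial, consuming the current RNG stream. Plain-list hot path.
replica_core <- function(n, sd_treatment, hypothesis, config,
                         pst_equal = NULL, need_measured = TRUE) {
  mu2 <- if (hypothesis == "H1") config$effect_size else 0
  x1 <- stats::rnorm(n, 0, 1)
  x2 <- stats::rnorm(n, mu2, sd_treatment)
  m1 <- mean(x1); s1 <- stats::sd(x1)
  m2 <- mean(x2); s2 <- stats::sd(x2)
  v1 <- s1^2 / n; v2 <- s2^2 / n
  se <- sqrt(v1 + v2)
  tt <- (m2 - m1) / se
  nu <- (v1 + v2)^2 / ((v1^2 + v2^2) / (n - 1))
  p  <- 2 * stats::pt(-abs(tt), df = nu)
  k  <- stationarity_k(config$prior, config$c_ratio)
  if (need_measured) {
    sol <- solve_pst_core(nu, config$effect_size * s1 / se, k,
                          config$prior, config$c_ratio)
    pm <- sol$pst; cm <- sol$converged
  } else {
    pm <- NA_real_; cm <- NA
  }
  list(p_value = p,
       pst_equal = if (is.null(pst_equal)) NA_real_ else pst_equal$pst,
       pst_measured = pm,
       converged_equal = if (is.null(pst_equal)) NA else pst_equal$converged,
       converged_measured = cm)
}

criterion_threshold <- function(criterion, rec) {
  switch(criterion,
    "fixed_0.05"        = 0.05,
    "fixed_0.005"       = 0.005,
    "flexible_equal"    = rec$pst_equal,
    "flexible_measured" = rec$pst_measured
  )
}

#' Run a single simulated trial replica
#'
#' Draws one two-arm Gaussian trial under the stated hypothesis using the
#' current RNG state (seed it with `set.seed()` for reproducibility),
#' analyzes it with Welch's t test, computes the flexible thresholds, and
#' records the significance decision under each criterion in `config`.
#' A study is significant iff its p value is strictly below the criterion's
#' threshold; a p value equal to or above the threshold counts as not
#' significant.
#'
#' @param n Per-arm sample size.
#' @param sd_treatment Treatment-arm SD (placebo SD is 1).
#' @param hypothesis `"H0"` (no effect) or `"H1"` (effect = config's
#'   `effect_size`).
#' @param config A [scenario_config()].
#' @return A one-row tibble: `p_value`, `pst_equal`, `pst_measured`,
#'   `converged_equal`, `converged_measured`, and one logical
#'   `sig_<criterion>` column per configured criterion.
#' @examples
#' set.seed(42)
#' run_replica(50, 2, "H1", scenario_config(n_reps = 1))
#' @export
run_replica <- function(n, sd_treatment, hypothesis = c("H0", "H1"), config) {
  hypothesis <- match.arg(hypothesis)
  stopifnot(inherits(config, "scenario_config"))
  need_eq <- "flexible_equal" %in% config$criteria
  need_me <- "flexible_measured" %in% config$criteria
  pst_eq <- if (need_eq) {
    solve_pst_core(2 * n - 2, config$effect_size * sqrt(n / 2),
                   stationarity_k(config$prior, config$c_ratio),
                   config$prior, config$c_ratio)
  }
  rec <- replica_core(n, sd_treatment, hypothesis, config, pst_eq, need_me)
  out <- tibble::as_tibble(rec)
  for (cr in config$criteria) {
    out[[paste0("sig_", cr)]] <- rec$p_value < criterion_threshold(cr, rec)
  }
  out
}

#' Run the full simulation grid
#'
#' For every combination of `n_per_arm` and `sd_treatment` in the config,
#' runs `n_reps` replicas under H0 and `n_reps` under H1 on independent,
#' reproducible substreams of the master seed, and summarizes each criterion:
#' the false-positive rate (share of H0 replicas declared significant), the
#' false-negative rate (share of H1 replicas declared not significant), and
#' the empirical weighted error
#' `c_ratio * prior * fn_rate + (1 - prior) * fp_rate`. Each summary row
#' combines the H0 and H1 substreams of one condition, so there is one row
#' per condition and criterion. For the flexible criteria the distribution
#' of the per-replica threshold (pooled over both hypotheses) is summarized
#' by its median and quartiles, and solver non-convergence is tallied in
#' `n_converged` rather than aborting the run.
#'
#' @param config A [scenario_config()].
#' @param progress If `TRUE`, prints one progress line per condition with
#'   replica and convergence tallies.
#' @return A `pst_simulation` tibble with columns `n_per_arm`,
#'   `sd_treatment`, `effect_size`, `prior`, `c_ratio`, `criterion`,
#'   `fp_rate`, `fn_rate`, `weighted_error`, `pst_median`, `pst_q25`,
#'   `pst_q75`, `n_converged`, `n_reps`, `seed`.
#' @examples
#' cfg <- scenario_config(n_per_arm = 50, sd_treatment = 1, n_reps = 200)
#' run_scenarios(cfg)
#' @export
run_scenarios <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  grid <- expand.grid(n = config$n_per_arm, sd_t = config$sd_treatment,
                      KEEP.OUT.ATTRS = FALSE)
  need_eq <- "flexible_equal" %in% config$criteria
  need_me <- "flexible_measured" %in% config$criteria
  k <- stationarity_k(config$prior, config$c_ratio)
  nr <- config$n_reps

  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    n <- grid$n[i]; sd_t <- grid$sd_t[i]
    pst_eq <- if (need_eq) {
      solve_pst_core(2 * n - 2, config$effect_size * sqrt(n / 2), k,
                     config$prior, config$c_ratio)
    }
    res <- list()
    for (hyp in c("H0", "H1")) {
      set.seed(substream_seed(config$seed, i, hyp))
      p  <- numeric(nr)
      pm <- numeric(nr)
      cm <- logical(nr)
      for (r in seq_len(nr)) {
        rec <- replica_core(n, sd_t, hyp, config, pst_eq, need_me)
        p[r]  <- rec$p_value
        pm[r] <- rec$pst_measured
        cm[r] <- isTRUE(rec$converged_measured)
      }
      res[[hyp]] <- list(p = p, pst_measured = pm, conv_measured = cm)
    }
    rows <- purrr::map_dfr(config$criteria, function(cr) {
      thr_h0 <- switch(cr,
        "fixed_0.05" = 0.05, "fixed_0.005" = 0.005,
        "flexible_equal" = rep(pst_eq$pst, nr),
        "flexible_measured" = res$H0$pst_measured)
      thr_h1 <- switch(cr,
        "fixed_0.05" = 0.05, "fixed_0.005" = 0.005,
        "flexible_equal" = rep(pst_eq$pst, nr),
        "flexible_measured" = res$H1$pst_measured)
      fp <- mean(res$H0$p < thr_h0)
      fn <- mean(res$H1$p >= thr_h1)
      psts <- switch(cr,
        "flexible_equal" = rep(pst_eq$pst, 2 * nr),
        "flexible_measured" = c(res$H0$pst_measured, res$H1$pst_measured),
        NULL)
      qs <- if (is.null(psts)) rep(NA_real_, 3) else
        stats::quantile(psts, c(0.5, 0.25, 0.75), names = FALSE, na.rm = TRUE)
      ncv <- switch(cr,
        "flexible_equal" = if (pst_eq$converged) 2L * nr else 0L,
        "flexible_measured" = sum(res$H0$conv_measured) + sum(res$H1$conv_measured),
        2L * nr)
      tibble::tibble(
        n_per_arm = n, sd_treatment = sd_t,
        effect_size = config$effect_size, prior = config$prior,
        c_ratio = config$c_ratio, criterion = cr,
        fp_rate = fp, fn_rate = fn,
        weighted_error = config$c_ratio * config$prior * fn +
          (1 - config$prior) * fp,
        pst_median = qs[1], pst_q25 = qs[2], pst_q75 = qs[3],
        n_converged = ncv, n_reps = nr, seed = config$seed
      )
    })
    if (progress) {
      message(sprintf(
        "condition n=%d sd2/sd1=%g: %d replicas x 2 hypotheses, %s",
        n, sd_t, nr,
        if (need_me) sprintf("measured-threshold solves converged %d/%d",
                             sum(res$H0$conv_measured) + sum(res$H1$conv_measured),
                             2L * nr)
        else "fixed thresholds only"))
    }
    out[[i]] <- rows
  }
  structure(dplyr::bind_rows(out),
            class = c("pst_simulation", class(tibble::tibble())))
}

#' Five-number box summary with 1.5 IQR whiskers
#'
#' Median and quartiles with whiskers at the most extreme data values within
#' 1.5 interquartile ranges of the quartiles; points beyond the whiskers are
#' listed as outliers. Quartiles use linear interpolation between order
#' statistics (`stats::quantile` type 7).
#'
#' @param values Numeric vector with at least one finite value.
#' @return A one-row tibble: `n`, `median`, `q25`, `q75`, `whisker_low`,
#'   `whisker_high`, `n_outliers`, and a list-column `outliers`.
#' @examples
#' box_stats(c(1:10, 50))
#' @export
box_stats <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) {
    rlang::abort("`values` must contain at least one finite value")
  }
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  tibble::tibble(
    n = length(values), median = q[2], q25 = q[1], q75 = q[3],
    whisker_low = min(values[inside]), whisker_high = max(values[inside]),
    n_outliers = sum(!inside), outliers = list(sort(values[!inside]))
  )
}

#' Weighted-error comparison plot for a simulation
#'
#' Stacked bars of the type I and type II contributions to the empirical
#' weighted error for each criterion, faceted by sample size and SD ratio.
#'
#' @param object A `pst_simulation` tibble from [run_scenarios()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pst_simulation <- function(object, ...) {
  df <- object |>
    dplyr::mutate(
      `type I`  = (1 - .data$prior) * .data$fp_rate,
      `type II` = .data$c_ratio * .data$prior * .data$fn_rate
    ) |>
    tidyr::pivot_longer(c("type I", "type II"),
                        names_to = "component", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$criterion, y = .data$value,
                                   fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(.data$sd_treatment ~ .data$n_per_arm,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "weighted error contribution", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
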
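#' Build a two-arm summary table from printed trial statistics
#'
#' Most published two-arm trials report only the per-arm sample size, mean,
#' and standard deviation. These are the sufficient statistics for everything
#' in this package: Welch's t test, the flexible significance threshold, and
#' the likelihood-ratio update all run off this table.
#'
#' @param n1,mean1,sd1 Sample size, mean, and standard deviation of the
#'   placebo (reference) arm. The minimum effect size of interest is expressed
#'   in units of `sd1`.
#' @param n2,mean2,sd2 The same statistics for the treatment arm.
#'
#' @return A tibble with columns `arm` (`"placebo"`, `"treatment"`), `n`,
#'   `mean`, `sd`; one row per arm, placebo first.
#'
#' @examples
#' arm_summaries(50, 11.1, 2.0, 50, 13.4, 4.3)
#' @export
arm_summaries <- function(n1, mean1, sd1, n2, mean2, sd2) {
  out <- tibble::tibble(
    arm  = c("placebo", "treatment"),
    n    = c(n1, n2),
    mean = c(mean1, mean2),
    sd   = c(sd1, sd2)
  )
  validate_arms(out)
}

#' Summarize raw per-arm observations
#'
#' Collapses raw outcome values (e.g. simulated draws, or individual patient
#' data) to the per-arm sufficient statistics. The standard deviation uses
#' the n - 1 denominator, matching standard trial reporting.
#'
#' @param data A data frame of individual observations.
#' @param value Unquoted column holding the outcome value.
#' @param arm Unquoted column identifying the arm. Arms are ordered so that a
#'   `"placebo"` label, if present, comes first; otherwise first-appearance
#'   order is kept and the first arm is treated as the reference.
#'
#' @return A tibble with columns `arm`, `n`, `mean`, `sd`, one row per arm.
#'
#' @examples
#' trial <- data.frame(
#'   arm = rep(c("placebo", "treatment"), each = 5),
#'   hb  = c(10.2, 11.5, 12.1, 10.8, 11.0, 12.9, 13.5, 14.1, 12.2, 13.8)
#' )
#' summarize_arms(trial, hb, arm)
#' @export
summarize_arms <- function(data, value, arm) {
  out <- data |>
    dplyr::group_by(arm = {{ arm }}) |>
    dplyr::summarise(
      n    = dplyr::n(),
      mean = mean({{ value }}),
      sd   = stats::sd({{ value }}),
      .groups = "drop"
    )
  out$arm <- as.character(out$arm)
  if ("placebo" %in% out$arm) {
    out <- out[order(out$arm != "placebo"), ]
  }
  if (any(out$n < 2)) {
    rlang::abort("every arm needs at least 2 observations")
  }
  out
}

#' Summarize a single numeric sample
#'
#' @param values Numeric vector with at least two elements.
#' @return A one-row tibble with columns `n`, `mean`, `sd` (n - 1 denominator).
#' @examples
#' summarize_sample(c(0, 2))
#' @export
summarize_sample <- function(values) {
  if (!is.numeric(values) || length(values) < 2L) {
    rlang::abort("`values` must be a numeric vector with at least 2 elements")
  }
  tibble::tibble(n = length(values), mean = mean(values), sd = stats::sd(values))
}

# Checks the two-arm table contract; returns the table (placebo row first).
validate_arms <- function(arms) {
  if (!is.data.frame(arms) || !all(c("n", "mean", "sd") %in% names(arms))) {
    rlang::abort("`arms` must be a data frame with columns n, mean, sd (see arm_summaries())")
  }
  if (nrow(arms) != 2L) {
    rlang::abort("`arms` must have exactly two rows (placebo and treatment)")
  }
  if ("arm" %in% names(arms) && "placebo" %in% arms$arm) {
    arms <- arms[order(arms$arm != "placebo"), ]
  }
  if (any(!is.finite(arms$n)) || any(arms$n < 2) || any(arms$n != round(arms$n))) {
    rlang::abort("per-arm `n` must be an integer >= 2")
  }
  if (any(!is.finite(arms$mean)) || any(!is.finite(arms$sd)) || any(arms$sd < 0)) {
    rlang::abort("per-arm `mean` must be finite and `sd` non-negative")
  }
  tibble::as_tibble(arms)
}
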
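#' Welch's unequal-variance two-sample t test from summary statistics
#'
#' Computes the Welch t statistic for the difference in means between the
#' treatment and placebo arms,
#' \deqn{t = (m_2 - m_1) / se_\Delta, \qquad
#'       se_\Delta = \sqrt{s_1^2/n_1 + s_2^2/n_2},}
#' with the Welch--Satterthwaite degrees of freedom
#' \deqn{\nu = \frac{(s_1^2/n_1 + s_2^2/n_2)^2}
#'       {(s_1^2/n_1)^2/(n_1-1) + (s_2^2/n_2)^2/(n_2-1)}}
#' and the two-tailed p value \eqn{2 F_\nu(-|t|)}. The degrees of freedom are
#' used as-is (generally non-integer); they are never rounded.
#'
#' @param arms Two-arm summary table, see [arm_summaries()].
#'
#' @return A one-row tibble with columns `estimate` (mean difference,
#'   treatment minus placebo), `t`, `se_delta`, `nu`, `p_two`.
#'
#' @examples
#' arm_summaries(50, 11.1, 2.0, 50, 13.4, 4.3) |> welch_test()
#' @export
welch_test <- function(arms) {
  arms <- validate_arms(arms)
  ws <- welch_stats(arms$n[1], arms$mean[1], arms$sd[1],
                    arms$n[2], arms$mean[2], arms$sd[2])
  tibble::tibble(
    estimate = ws$estimate, t = ws$t, se_delta = ws$se_delta,
    nu = ws$nu, p_two = ws$p_two
  )
}

# Fast list-returning core shared with the simulator (no tibble overhead).
welch_stats <- function(n1, m1, s1, n2, m2, s2) {
  v1 <- s1^2 / n1
  v2 <- s2^2 / n2
  if (v1 + v2 <= 0) {
    rlang::abort("both arms have zero standard deviation; the test statistic is undefined")
  }
  se <- sqrt(v1 + v2)
  t  <- (m2 - m1) / se
  nu <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(
    estimate = m2 - m1, t = t, se_delta = se, nu = nu,
    p_two = 2 * stats::pt(-abs(t), df = nu)
  )
}
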
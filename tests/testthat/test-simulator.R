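test_that("scenario_config validates its inputs", {
  cfg <- scenario_config(n_per_arm = 50, sd_treatment = 1, n_reps = 10)
  expect_s3_class(cfg, "scenario_config")
  expect_error(scenario_config(criteria = character(0)), "non-empty subset")
  expect_error(scenario_config(criteria = "fixed_0.5"), "non-empty subset")
  expect_error(scenario_config(n_per_arm = 1), ">= 2")
  expect_error(scenario_config(sd_treatment = -1), "positive")
  expect_error(scenario_config(n_reps = 0), "positive integer")
  expect_error(scenario_config(prior = 1.2), "between 0 and 1")
})

test_that("replicas and scenario summaries are reproducible bit for bit", {
  cfg <- scenario_config(n_per_arm = 50, sd_treatment = 2, n_reps = 30, seed = 9)
  set.seed(123)
  a <- run_replica(50, 2, "H1", cfg)
  set.seed(123)
  b <- run_replica(50, 2, "H1", cfg)
  expect_identical(a, b)

  s1 <- run_scenarios(cfg)
  s2 <- run_scenarios(cfg)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  # and different substreams genuinely differ
  cfg2 <- scenario_config(n_per_arm = 50, sd_treatment = 2, n_reps = 30, seed = 10)
  expect_false(identical(run_scenarios(cfg2)$fp_rate, s1$fp_rate))
})

test_that("a zero effect size makes H1 draws distributionally identical to H0", {
  cfg <- scenario_config(n_per_arm = 40, sd_treatment = 1.5, effect_size = 0,
                         criteria = c("fixed_0.05", "fixed_0.005"), n_reps = 5)
  set.seed(77)
  h0 <- run_replica(40, 1.5, "H0", cfg)
  set.seed(77)
  h1 <- run_replica(40, 1.5, "H1", cfg)
  expect_identical(h0, h1)
})

test_that("fixed criteria hit their nominal false-positive rates under H0", {
  cfg <- scenario_config(n_per_arm = 100, sd_treatment = 1,
                         criteria = c("fixed_0.05", "fixed_0.005"),
                         n_reps = 2000, seed = 42)
  s <- run_scenarios(cfg)
  fp05 <- s$fp_rate[s$criterion == "fixed_0.05"]
  fp005 <- s$fp_rate[s$criterion == "fixed_0.005"]
  expect_lt(abs(fp05 - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
  expect_lt(abs(fp005 - 0.005), 3 * sqrt(0.005 * 0.995 / 2000))
  expect_equal(s$weighted_error,
               0.25 * 0.5 * s$fn_rate + 0.5 * s$fp_rate, tolerance = 1e-12)

  # equal variances: the empirical miss rate matches the shifted-t power
  # formula at the 0.05 critical value (the formula is itself approximate)
  x05 <- qt(0.975, df = 198)
  beta_formula <- beta_of_x(x05, 198, 0.5 * sqrt(50))
  expect_lt(abs(s$fn_rate[s$criterion == "fixed_0.05"] - beta_formula), 0.03)
})

test_that("larger trials miss fewer real effects", {
  cfg <- scenario_config(n_per_arm = c(50, 200, 800), sd_treatment = 1,
                         criteria = c("fixed_0.05", "flexible_measured"),
                         n_reps = 500, seed = 5)
  s <- run_scenarios(cfg)
  for (cr in unique(s$criterion)) {
    fn <- s$fn_rate[s$criterion == cr][order(s$n_per_arm[s$criterion == cr])]
    slack <- 3 * sqrt(0.25 * 0.75 / 500)
    expect_true(all(diff(fn) < slack))
  }
  # at n = 800 a medium effect is essentially never missed
  expect_lt(max(s$fn_rate[s$n_per_arm == 800]), 0.01)
})

test_that("solver convergence is tallied per condition", {
  cfg <- scenario_config(n_per_arm = 50, sd_treatment = 1,
                         criteria = "flexible_measured", n_reps = 50, seed = 2)
  s <- run_scenarios(cfg)
  expect_equal(s$n_converged, 100L)  # both hypotheses
  expect_true(is.finite(s$pst_median))
  expect_lte(s$pst_q25, s$pst_median)
  expect_lte(s$pst_median, s$pst_q75)
})

test_that("box_stats implements the 1.5 IQR whisker rule", {
  cst <- box_stats(rep(0.3, 8))
  expect_equal(unlist(cst[c("median", "q25", "q75", "whisker_low", "whisker_high")]),
               rep(0.3, 5), ignore_attr = TRUE)
  expect_equal(cst$n_outliers, 0L)

  b <- box_stats(1:100)
  expect_equal(b$median, 50.5)
  # type-7 linear interpolation between order statistics
  expect_equal(b$q25, 25.75)
  expect_equal(b$q75, 75.25)
  expect_equal(b$whisker_low, 1)
  expect_equal(b$whisker_high, 100)
  expect_equal(b$n_outliers, 0L)

  o <- box_stats(c(1:10, 50))
  expect_equal(o$n_outliers, 1L)
  expect_equal(o$outliers[[1]], 50)
  expect_equal(o$whisker_high, 10)

  expect_error(box_stats(numeric(0)), "at least one")
  expect_error(box_stats(NA_real_), "at least one")
})

test_that("config round-trips through YAML and JSON files", {
  cfg <- scenario_config(n_per_arm = c(50, 100), sd_treatment = c(1, 2),
                         criteria = "fixed_0.05", n_reps = 25, seed = 4)
  y <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(cfg), y)
  expect_equal(read_scenario_config(y), cfg)

  j <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(unclass(cfg), j, auto_unbox = TRUE)
  expect_equal(read_scenario_config(j), cfg)

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines("x", bad)
  expect_error(read_scenario_config(bad), "yaml")
})

test_that("plots build without evaluation errors", {
  fit <- flexible_pst(replica1_arms())
  p1 <- ggplot2::autoplot(fit)
  expect_s3_class(p1, "ggplot")
  cfg <- scenario_config(n_per_arm = 50, sd_treatment = 1, n_reps = 20, seed = 1)
  p2 <- ggplot2::autoplot(run_scenarios(cfg))
  expect_s3_class(p2, "ggplot")
  expect_no_error(ggplot2::ggplot_build(p1))
  expect_no_error(ggplot2::ggplot_build(p2))
})
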
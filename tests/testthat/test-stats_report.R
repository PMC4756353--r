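test_that("the paired log t-test matches hand and reference computations", {
  ctrl <- c(310, 280, 150)
  trt <- c(120, 200, 90)
  res <- paired_log_t_test(ctrl, trt)
  expect_equal(res$t, hand_paired_log_t(ctrl, trt), tolerance = 1e-10)
  # against the reference implementation, on 100 random paired tables
  set.seed(77)
  for (i in 1:100) {
    n <- sample(3:10, 1)
    c0 <- exp(rnorm(n, 5, 1)); t0 <- exp(rnorm(n, 4.6, 1))
    mine <- paired_log_t_test(c0, t0, "two_sided")
    ref <- t.test(log(c0), log(t0), paired = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-6)
    ref1 <- t.test(log(c0), log(t0), paired = TRUE, alternative = "greater")
    expect_equal(paired_log_t_test(c0, t0)$p_value, ref1$p.value,
                 tolerance = 1e-6)
  }
})

test_that("the t statistic is invariant to common rescaling and guards degeneracy", {
  ctrl <- c(9.1, 4.2, 7.7, 5.0)
  trt <- c(5.5, 3.9, 2.2, 4.8)
  base <- paired_log_t_test(ctrl, trt)
  scaled <- paired_log_t_test(1000 * ctrl, 1000 * trt)
  expect_equal(scaled$t, base$t, tolerance = 1e-12)
  expect_equal(scaled$p_value, base$p_value, tolerance = 1e-12)
  expect_error(paired_log_t_test(exp(1) * trt, trt), "zero variance")
  expect_error(paired_log_t_test(c(1, -2), c(1, 2)), "positive")
  expect_error(paired_log_t_test(1, 2), "at least 2")
})

test_that("percent change supports per-pair and group-mean conventions", {
  halved <- data.frame(control = c(10, 50, 80), treated = c(5, 25, 40))
  pp <- percent_change(pairs = halved)
  expect_equal(pp$mean, -50)
  expect_equal(pp$sd, 0)
  expect_equal(round(percent_change(
    group_means = c(control = 813.6, treated = 1103.4))), 36)
  # conventions agree exactly iff all controls are equal
  eqc <- data.frame(control = c(10, 10), treated = c(12, 18))
  expect_equal(percent_change(pairs = eqc)$mean,
               percent_change(group_means = c(control = 10, treated = 15)))
  hetero <- data.frame(control = c(10, 100), treated = c(20, 110))
  expect_false(isTRUE(all.equal(
    percent_change(pairs = hetero)$mean,
    percent_change(group_means = c(control = 55, treated = 65)))))
  expect_error(percent_change(pairs = data.frame(control = 0, treated = 1)),
               "zero control")
})

test_that("paired comparisons bundle the reported quantities coherently", {
  set.seed(5)
  ctrl <- exp(rnorm(8, 5.5, 0.8))
  trt <- ctrl * runif(8, 0.3, 0.7)
  cmp <- paired_comparison(ctrl, trt, label = "factin_density")
  expect_equal(cmp$n, 8)
  expect_lt(cmp$per_pair_pct_mean, 0)
  expect_equal(cmp$group_mean_pct_rounded, round(cmp$group_mean_pct))
  expect_lt(cmp$p_value, 0.05)
  df <- as.data.frame(cmp)
  expect_equal(df$measure, "factin_density")
})

test_that("reports are complete and byte-identical across reruns", {
  set.seed(9)
  ctrl <- exp(rnorm(6, 5, 1)); trt <- ctrl * runif(6, 0.4, 0.6)
  results <- list(
    density = paired_comparison(ctrl, trt, label = "density"),
    distribution = paired_comparison(ctrl * 2, trt, label = "distribution"),
    pores = pore_summary(list(areas_um2 = c(700, 900)),
                         list(areas_um2 = c(1000, 1200))),
    viability = data.frame(condition = c("control", "treated"),
                           percent_live = c(78.7, 70.0)))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- build_report(results, d1, config = list(seed = 1), seed = 1)
  f2 <- build_report(results, d2, config = list(seed = 1), seed = 1)
  expect_setequal(basename(list.files(d1)),
                  c("density_table.csv", "distribution_table.csv",
                    "pore_summary.csv", "viability_summary.csv",
                    "run_log.txt"))
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # density-only run emits just that table plus the log
  d3 <- withr::local_tempdir()
  build_report(list(density = results$density), d3)
  expect_setequal(basename(list.files(d3)),
                  c("density_table.csv", "run_log.txt"))
  expect_error(build_report(list(), tempdir()), "no results")
})
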
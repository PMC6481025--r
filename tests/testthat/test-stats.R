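test_that("Mann-Whitney matches hand-enumerated small cases", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 2 / 6, tolerance = 1e-12)
  expect_equal(r$method, "exact")
  # identical multisets: perfect overlap, p = 1 (tie-corrected path)
  r2 <- mann_whitney(c(5, 6, 7), c(5, 6, 7))
  expect_equal(r2$p_value, 1)
  expect_equal(r2$method, "normal_approx_tie_corrected")
})

test_that("exact p equals the full rank-split enumeration oracle", {
  set.seed(100)
  for (rep in 1:30) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- runif(n1); y <- runif(n2)  # continuous: no ties
    r <- mann_whitney(x, y)
    expect_equal(r$method, "exact")
    expect_equal(r$p_value, mw_enum_p(x, y), tolerance = 1e-12)
    # U bounds and the complementarity identity
    ry <- mann_whitney(y, x)
    expect_gte(r$statistic, 0)
    expect_lte(r$statistic, n1 * n2)
    expect_equal(r$statistic + ry$statistic, n1 * n2)
    expect_equal(ry$p_value, r$p_value, tolerance = 1e-12)
  }
})

test_that("exact and approximate branches agree near the threshold", {
  # The worst-case two-sided discrepancy between the exact distribution and
  # the continuity-corrected normal approximation at n1 = n2 = 8, computed
  # by sweeping every achievable U against pwilcox, is 0.0110; every random
  # dataset must stay within it and typical ones well inside.
  set.seed(200)
  diffs <- replicate(20, {
    x <- rnorm(8); y <- rnorm(8)
    exact <- mann_whitney(x, y, exact_threshold = 16)
    approx <- mann_whitney(x, y, exact_threshold = 10)
    expect_equal(exact$method, "exact")
    expect_equal(approx$method, "normal_approx_tie_corrected")
    abs(exact$p_value - approx$p_value)
  })
  expect_lt(max(diffs), 0.0110)
  expect_lt(stats::median(diffs), 0.01)
})

test_that("Mann-Whitney agrees with the base-R reference on tied data", {
  set.seed(9)
  x <- sample(1:6, 12, replace = TRUE)
  y <- sample(2:8, 15, replace = TRUE)
  r <- mann_whitney(x, y)
  ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE))
  expect_equal(r$statistic, unname(ref$statistic))
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("OLS matches the normal-equations closed form", {
  # perfect fit (summary.lm warns about it; the numbers are still exact)
  x <- 1:5
  r <- suppressWarnings(ols_regression(x, 2 * x + 1))
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_equal(r$intercept, 1, tolerance = 1e-12)
  expect_equal(r$r_squared, 1)
  # constant response
  rc <- ols_regression(x, rep(3, 5))
  expect_equal(rc$slope, 0)
  expect_equal(rc$r_squared, 0)
  # random data vs closed form
  set.seed(77)
  for (rep in 1:5) {
    x <- rnorm(20); y <- 1.5 * x + rnorm(20)
    r <- ols_regression(x, y)
    o <- ols_closed_form(x, y)
    for (f in names(o)) expect_equal(r[[f]], o[[f]], tolerance = 1e-10)
  }
  expect_error(ols_regression(rep(1, 5), rnorm(5)), "constant")
  expect_error(ols_regression(1:2, 1:2), "at least 3")
})

test_that("the case-series table reproduces the published demographics", {
  t1 <- fabry_table1()
  expect_equal(nrow(t1), 11L)
  d <- summarize_demographics(t1)
  expect_equal(round(d$age_mean, 1), 51.7)
  expect_equal(round(d$age_sd, 1), 15.6)
  expect_equal(d$age_min, 30)
  expect_equal(d$age_max, 71)
  expect_equal(d$n_male, 5L)
  expect_equal(d$n_female, 6L)
  # single subject: SD undefined
  ds <- summarize_demographics(t1[1, , drop = FALSE])
  expect_true(is.na(ds$age_sd))
})

test_that("aggregation averages segments within eye, then across eyes", {
  mt <- data.frame(
    subject_id = c(rep("s1", 7), rep("s2", 2)),
    eye = c(rep("OD", 5), "OS", "OS", "OD", "OD"),
    site = "retina",
    segment_id = as.character(1:9),
    soam = c(0.10, 0.12, 0.14, 0.10, 0.09, 0.20, 0.30, 0.5, 0.7),
    pad = 1, i2e = 1)
  # single-eye subject s2 is kept, with a warning
  expect_warning(agg <- aggregate_to_subject(mt), "single-eye")
  s1 <- agg$soam[agg$subject_id == "s1"]
  expect_equal(s1, (mean(c(0.10, 0.12, 0.14, 0.10, 0.09)) +
                      mean(c(0.20, 0.30))) / 2)
  expect_equal(agg$soam[agg$subject_id == "s2"], 0.6)
  # per-eye unit keeps eyes separate
  eye <- aggregate_to_subject(mt, unit = "eye")
  expect_equal(nrow(eye), 3L)
})

test_that("run_study covers every configured comparison or records a skip", {
  co <- gen_cohort(cohort_params(n_per_group = 6,
                                 sites = c("retina", "conj_nasal"),
                                 rng_seed = 14))
  mt <- tortuosity_table(co)
  rep <- run_study(mt, co$subjects)
  # 2 sites x 3 metrics x (FD-vs-control + MvF FD + MvF control)
  expect_equal(nrow(rep$tests), 2L * 3L * 3L)
  expect_true(all(rep$tests$p_value > 0 & rep$tests$p_value <= 1))
  # no systemic covariates in a simulated cohort: gfr and mwt are skipped
  sysk <- rep$skipped$reason[rep$skipped$comparison == "systemic_FD"]
  expect_true(any(grepl("gfr", sysk)))
  expect_true(any(grepl("mwt", sysk)))
  # age regressions per group, plus retina-vs-conjunctiva per metric
  expect_equal(sum(rep$regressions$comparison %in%
                     c("age_FD", "age_control")), 2L * 3L * 2L)
  expect_equal(sum(rep$regressions$comparison == "retina_vs_conjunctiva"),
               3L)
})

test_that("an injected effect is detected at the affected site", {
  co <- gen_cohort(cohort_params(n_per_group = 11,
                                 sites = c("retina", "conj_temporal"),
                                 effect_multiplier = c(retina = 2,
                                                       conj_temporal = 1),
                                 rng_seed = 42))
  rep <- run_study(tortuosity_table(co), co$subjects)
  fdc <- rep$tests[rep$tests$comparison == "FD_vs_control", ]
  expect_true(all(fdc$p_value[fdc$site == "retina"] < 0.05))
})

test_that("metrics referencing unknown subjects are rejected", {
  co <- gen_cohort(cohort_params(n_per_group = 2, sites = "retina",
                                 rng_seed = 3))
  mt <- tortuosity_table(co)
  bad <- co$subjects[-1, ]
  expect_error(run_study(mt, bad), "absent")
})
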
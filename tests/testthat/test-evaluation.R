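test_that("stratified splits have fixed sizes and event counts", {
  ev <- c(rep(1, 10), rep(0, 90))
  plan <- bootstrap_plan(n_rounds = 5, seed = 3)
  sp <- stratified_splits(ev, plan)
  for (s in sp) {
    expect_length(s$test, 20L)
    expect_equal(sum(ev[s$test]), 2)
    expect_length(intersect(s$train, s$test), 0L)
    # stratification invariant
    expect_lt(abs(mean(ev[s$test]) - mean(ev)), 1 / length(s$test))
  }
  expect_identical(stratified_splits(ev, plan), sp)
  expect_error_class(stratified_splits(rep(0, 10), plan),
                     "strisk_config_error")
})

test_that("a 4395-patient cohort with 149 events yields 3516 training rows", {
  ev <- c(rep(1, 149), rep(0, 4246))
  sp <- stratified_splits(ev, bootstrap_plan(n_rounds = 3, seed = 1))
  expect_true(all(vapply(sp, function(s) length(s$train), 0L) == 3516L))
})

test_that("AUC examples and oracle agreement", {
  expect_equal(auc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(auc(rep(0.5, 6), c(1, 0, 1, 0, 0, 1)), 0.5)
  expect_error_class(auc(1:4, rep(1, 4)), "strisk_parameter_error")
  set.seed(4)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(seq_len(max(2, n %/% 2)), n, replace = TRUE)  # forces ties
    expect_equal(auc(s, y), oracle_auc(s, y), tolerance = 1e-12)
  }
})

test_that("Hanley-McNeil interval formula and monotonicity", {
  ci <- hanley_mcneil_ci(0.5, 10, 10)
  expect_equal(ci$se, sqrt(0.0175), tolerance = 1e-12)
  expect_equal(ci$lower, 0.5 - 1.96 * sqrt(0.0175))
  expect_equal(ci$upper, 0.5 + 1.96 * sqrt(0.0175))
  # symmetric about A before clipping
  expect_equal(ci$upper - 0.5, 0.5 - ci$lower)
  expect_equal(hanley_mcneil_ci(1, 5, 5)$se, 0)
  expect_equal(hanley_mcneil_ci(1, 5, 5)$lower, 1)
  ses <- vapply(c(10, 100, 1000),
                function(n) hanley_mcneil_ci(0.7, n, n)$se, 0)
  expect_true(all(diff(ses) < 0))
})

test_that("upper-quartile dichotomization and cutoff truncation", {
  d <- dichotomize_upper_quartile(1:8)
  expect_equal(d$cutoff, 6.25)
  expect_equal(which(d$high_risk == 1L), c(7L, 8L))
  expect_equal(dichotomize_upper_quartile(1:8,
                                          external_cutoff = 0.2736)$cutoff,
               0.2)
  expect_equal(dichotomize_upper_quartile(1:8,
                                          external_cutoff = 0.0734)$cutoff,
               0.07)
  expect_equal(truncate_sig(c(0.2736, 0.0734, 3.9)), c(0.2, 0.07, 3))
  expect_error_class(dichotomize_upper_quartile(1:3),
                     "strisk_parameter_error")
})

test_that("Cox hazard ratios: symmetry, censoring rule, failure flags", {
  # identical outcome pattern in both groups -> HR 1
  tt <- rep(c(30, 60, 365, 365), 2)
  ev <- rep(c(1, 1, 0, 0), 2)
  grp <- rep(c(0, 1), each = 4)
  cx <- cox_hr(grp, tt, ev, 365)
  expect_true(cx$ok)
  expect_equal(cx$hr, 1, tolerance = 1e-6)

  # event after the horizon is censored at the horizon
  tt2 <- c(10, 400, 200, 365, 50, 365)
  ev2 <- c(1, 1, 0, 0, 1, 0)
  g2 <- c(1, 1, 1, 0, 0, 0)
  fit_manual <- survival::coxph(
    survival::Surv(pmin(tt2, 365), as.integer(ev2 == 1 & tt2 <= 365)) ~ g2)
  cx2 <- cox_hr(g2, tt2, ev2, 365)
  expect_equal(cx2$hr, unname(exp(coef(fit_manual))), tolerance = 1e-8)

  expect_false(cox_hr(rep(1, 4), c(1, 2, 3, 4), c(1, 1, 0, 0), 365)$ok)
  expect_false(cox_hr(c(0, 0, 1, 1), c(400, 400, 400, 400),
                      c(1, 1, 1, 1), 365)$ok)
})

test_that("Cox recovery on a small parametric simulation", {
  set.seed(6)
  hrs <- vapply(1:20, function(i) {
    n <- 1000
    g <- rbinom(n, 1, 0.25)
    tt <- rexp(n, rate = 0.0003 * 3^g)
    ev <- as.integer(tt <= 365)
    cox_hr(g, pmin(tt, 365), ev, 365)$hr
  }, 0)
  expect_gt(median(hrs), 2.4)
  expect_lt(median(hrs), 3.7)
})

test_that("NRI formula, constructors and bounds", {
  counts <- list(events = list(n = 4, up = 2, down = 1),
                 nonevents = list(n = 10, up = 1, down = 3))
  expect_equal(nri(counts), 0.45)
  expect_equal(nri(list(events = list(n = 5, up = 0, down = 0),
                        nonevents = list(n = 5, up = 0, down = 0))), 0)
  expect_equal(nri(list(events = list(n = 3, up = 3, down = 0),
                        nonevents = list(n = 4, up = 0, down = 4))), 2)
  expect_error_class(nri(list(events = list(n = 0, up = 0, down = 0),
                              nonevents = list(n = 1, up = 0, down = 0))),
                     "strisk_parameter_error")

  ev <- c(1, 1, 1, 1, rep(0, 10))
  old <- c(0, 0, 1, 1, rep(0, 5), rep(1, 5))
  new <- c(1, 1, 1, 0, c(0, 0, 0, 0, 1), c(1, 0, 0, 0, 1))
  # events: 2 up, 1 down of 4; nonevents: 1 up, 3 down of 10
  expect_equal(nri_from_classes(old, new, ev), 0.45)

  # category-free: all events up, all nonevents down -> 2
  expect_equal(nri_category_free(c(0.4, 0.4, 0.6, 0.6),
                                 c(0.5, 0.5, 0.5, 0.5),
                                 c(1, 1, 0, 0)), 2)
})

test_that("NRI is centred at zero under label-independent reclassification", {
  set.seed(7)
  vals <- vapply(1:20, function(i) {
    n <- 5000
    ev <- rbinom(n, 1, 0.3)
    nri_category_free(runif(n), runif(n), ev)
  }, 0)
  expect_lt(abs(mean(vals)), 0.02)
})

test_that("Kaplan-Meier estimates match hand product-limit values", {
  km0 <- km_curve(c(10, 20, 30, 40), c(0, 0, 0, 0), rep("a", 4),
                  horizon_days = 60)
  expect_true(all(km0$curve$survival == 1))

  km1 <- km_curve(c(1, 2, 5, 5), c(1, 1, 0, 0), rep("a", 4),
                  horizon_days = 60, ticks = c(0, 3))
  s1 <- km1$curve$survival[km1$curve$time == 1]
  s2 <- km1$curve$survival[km1$curve$time == 2]
  expect_equal(s1, 0.75)
  expect_equal(s2, 0.5)
  expect_equal(km1$at_risk$at_risk, c(4L, 2L))

  km2 <- km_curve(c(0, 0, 0), c(1, 1, 1), rep("a", 3), horizon_days = 60)
  expect_equal(min(km2$curve$survival), 0)

  kmg <- km_curve(c(5, 10, 20, 30), c(1, 0, 1, 0), c("a", "a", "b", "b"),
                  horizon_days = 60)
  expect_setequal(unique(kmg$curve$group), c("a", "b"))
})

test_that("paired comparison p-values behave", {
  a <- rnorm(100)
  expect_equal(paired_compare(a, a), 1)
  expect_lt(suppressWarnings(paired_compare(a, a + 0.05)), 1e-10)
  # constant non-zero shift with zero variance: degenerate p of 0, warned
  expect_warning(p0 <- paired_compare(c(1, 2, 3), c(2, 3, 4)),
                 "degenerate")
  expect_equal(p0, 0)
  set.seed(8)
  rej <- mean(vapply(1:200, function(i)
    paired_compare(rnorm(1000), rnorm(1000)) < 0.05, TRUE))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})

test_that("run_benchmark: empty plan, determinism, output shape", {
  r0 <- run_benchmark(small_cohort, models = "lr_hx",
                      plan = bootstrap_plan(n_rounds = 0))
  expect_s3_class(r0, "bootstrap_result")
  expect_equal(nrow(r0$auc), 0L)

  plan <- bootstrap_plan(n_rounds = 2, seed = 5, horizons = 365)
  a <- suppressWarnings(
    run_benchmark(small_cohort, models = c("lr_hx", "trs"), plan = plan))
  b <- suppressWarnings(
    run_benchmark(small_cohort, models = c("lr_hx", "trs"), plan = plan))
  expect_identical(a$auc, b$auc)
  expect_identical(a$hr, b$hr)
  expect_true(all(c("round", "model", "auc", "se", "lower", "upper") %in%
                    names(a$auc)))
  expect_true(all(a$auc$auc >= 0 & a$auc$auc <= 1))
})
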
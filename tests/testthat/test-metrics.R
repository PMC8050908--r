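test_that("Kaplan-Meier estimator reproduces product-limit hand values", {
  km <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$breakpoints, c(1, 2, 3))
  expect_equal(km$values, c(2 / 3, 1 / 3, 0))

  # censoring at t = 2 causes no drop, only shrinks the risk set
  km2 <- kaplan_meier(c(1, 2), c(1, 0))
  expect_equal(km2$breakpoints, 1)
  expect_equal(km2$values, 0.5)
  expect_equal(curve_eval(km2, c(1.5, 5)), c(0.5, 0.5))

  # no events: S == 1 everywhere
  km3 <- kaplan_meier(c(2, 4, 6), c(0, 0, 0))
  expect_equal(curve_eval(km3, c(0, 3, 10)), c(1, 1, 1))

  expect_error(kaplan_meier(c(-1, 2), c(1, 1)), "positive")
})

test_that("KM matches the brute-force oracle and survfit on random data", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(3:20, 1)
    time <- sample(1:10, n, replace = TRUE)        # force ties
    event <- rbinom(n, 1, 0.6)
    km <- kaplan_meier(time, event)
    oracle <- km_oracle(time, event)
    expect_equal(km$breakpoints, oracle$breakpoints)
    expect_equal(km$values, oracle$values, tolerance = 1e-12)
  }
  # independent cross-check against the survival package
  time <- c(3, 3, 5, 7, 7, 9, 12)
  event <- c(1, 0, 1, 1, 1, 0, 1)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  km <- kaplan_meier(time, event)
  expect_equal(curve_eval(km, sf$time), sf$surv, tolerance = 1e-12)
})

test_that("rectangle-sum areas match closed forms and refine with dx", {
  unit <- step_curve(numeric(0), numeric(0), domain_end = 10)
  expect_equal(curve_area(unit, dx = 0.1, t_max = 10), 10)

  zero <- step_curve(1e-12 + 1e-6, 0, domain_end = 10)
  expect_lt(curve_area(zero, dx = 0.1, t_max = 10), 0.11)

  half <- step_curve(5, 0.5, domain_end = 10)
  expect_lt(abs(curve_area(half, dx = 0.1, t_max = 10) - 7.5), 0.1)

  # per-curve the error obeys the documented bound dx * n_bp * max jump;
  # halving dx halves the error in expectation (checked on the mean over
  # random curves at a fixed seed)
  set.seed(4)
  errs <- sapply(1:40, function(i) {
    bp <- sort(runif(5, 0.05, 9.5))
    vals <- sort(runif(5), decreasing = TRUE)
    cv <- step_curve(bp, vals, domain_end = 10)
    exact <- sum(diff(c(0, bp, 10)) * c(1, vals))
    err <- function(dx) abs(curve_area(cv, dx = dx, t_max = 10) - exact)
    max_jump <- max(abs(diff(c(1, vals))))
    expect_lte(err(0.1), 0.1 * 5 * max_jump + 1e-12)
    expect_lte(err(0.05), 0.05 * 5 * max_jump + 1e-12)
    c(err(0.1), err(0.05))
  })
  expect_lte(mean(errs[2, ]), 0.5 * mean(errs[1, ]) + 1e-12)
})

test_that("curve IoU matches closed forms and is a symmetric ratio in [0,1]", {
  a <- kaplan_meier(c(1, 4, 7), c(1, 1, 1))
  expect_equal(curve_iou(a, a), 1, tolerance = 1e-12)

  unit <- step_curve(numeric(0), numeric(0), domain_end = 10)
  half <- step_curve(1e-9 + 1e-9, 0.5, domain_end = 10)
  expect_lt(abs(curve_iou(unit, half) - 0.5), 0.011)

  set.seed(12)
  for (i in 1:20) {
    c1 <- kaplan_meier(runif(15, 0.1, 10), rbinom(15, 1, 0.7))
    c2 <- kaplan_meier(runif(10, 0.1, 12), rbinom(10, 1, 0.7))
    iou <- curve_iou(c1, c2)
    expect_gte(iou, 0)
    expect_lte(iou, 1)
    expect_equal(iou, curve_iou(c2, c1))
  }
})

test_that("degrading predictions monotonically decreases mean IoU", {
  set.seed(8)
  truth_times <- rexp(300, 0.1)
  truth <- kaplan_meier(truth_times, rep(1, 300))
  mean_iou <- sapply(c(1, 2, 4, 8), function(f) {
    mean(replicate(5, {
      pred <- rexp(300, 0.1) * f
      curve_iou(kaplan_meier(pred, rep(1, 300)), truth)
    }))
  })
  expect_true(all(diff(mean_iou) < 0))
})

test_that("RMSE and Lin's CCC match hand and oracle values", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(3, 4), c(1, 2)), 2)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_error(rmse(1:3, 1:2), "length")

  x <- c(1, 2, 3)
  expect_equal(ccc(x, x), 1)
  expect_equal(ccc(c(-1, 0, 1), c(1, 0, -1)), -1)

  pred <- c(1, 2, 3); truth <- c(2, 2, 2.5)
  oracle <- 2 * cov(pred, truth) /
    (var(pred) + var(truth) + (mean(pred) - mean(truth))^2)
  expect_equal(ccc(pred, truth), oracle)
  expect_error(ccc(c(1, 1), c(1, 2)), "variance")
})

test_that("|CCC| <= |Pearson correlation| on random inputs (Lin)", {
  set.seed(5)
  for (i in 1:50) {
    a <- rnorm(20); b <- 0.5 * a + rnorm(20) + runif(1, -2, 2)
    expect_lte(abs(ccc(a, b)), abs(cor(a, b)) + 1e-12)
  }
})

test_that("step curves validate and export", {
  expect_error(step_curve(c(2, 1), c(0.5, 0.4)), "increasing")
  expect_error(step_curve(c(1, 2), c(0.4, 0.5)), "non-increasing")
  expect_error(step_curve(1, 1.5), "\\[0, 1\\]")

  km <- kaplan_meier(c(1, 2), c(1, 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_step_curve(km, path)
  tab <- read.delim(path)
  expect_equal(tab$time, c(0, 1, 2))
  expect_equal(tab$survival, c(1, 0.5, 0))
})
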
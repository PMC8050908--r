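test_that("Cox loss reproduces hand-computed partial-likelihood values", {
  expect_equal(cox_npll(c(0, 0), time = c(1, 2), event = c(1, 1)), log(2),
               tolerance = 1e-12)
  expect_equal(cox_npll(c(0, 0, 0), time = c(1, 2, 3), event = c(1, 0, 1)),
               log(3), tolerance = 1e-12)
  # singleton risk set contributes zero
  expect_equal(cox_npll(1.7, time = 4, event = 1), 0)
  expect_error(cox_npll(c(0, 0), c(1, 2), c(0, 0)), "event")
})

test_that("Cox loss agrees with a direct risk-set oracle, ties included", {
  set.seed(41)
  for (i in 1:30) {
    n <- sample(3:12, 1)
    time <- sample(1:6, n, replace = TRUE)    # heavy ties (Breslow sharing)
    event <- rbinom(n, 1, 0.7); event[sample(n, 1)] <- 1
    h <- rnorm(n)
    expect_equal(cox_npll(h, time, event), cox_npll_oracle(h, time, event),
                 tolerance = 1e-10)
  }
})

test_that("analytic Cox gradient matches central finite differences", {
  set.seed(17)
  for (i in 1:10) {
    n <- sample(4:10, 1)
    time <- round(rexp(n) + 0.1, 2)
    event <- rbinom(n, 1, 0.6); event[sample(n, 1)] <- 1
    h <- rnorm(n)
    g <- coxdistnet:::cox_npll_grad(h, time, event)$grad
    eps <- 1e-6
    fd <- vapply(seq_len(n), function(k) {
      hp <- h; hm <- h
      hp[k] <- h[k] + eps; hm[k] <- h[k] - eps
      (cox_npll(hp, time, event) - cox_npll(hm, time, event)) / (2 * eps)
    }, numeric(1))
    expect_equal(g, fd, tolerance = 1e-5)
  }
})

test_that("partial likelihood is invariant to log-risk shifts", {
  set.seed(23)
  time <- rexp(15) + 0.1
  event <- rbinom(15, 1, 0.7); event[1] <- 1
  h <- rnorm(15)
  for (c0 in c(-100, -3, 0.5, 42)) {
    expect_equal(cox_npll(h + c0, time, event), cox_npll(h, time, event),
                 tolerance = 1e-9)
  }
})

test_that("with one event the loss depends only on that event's risk set", {
  time <- c(5, 1, 3, 8)
  event <- c(0, 0, 1, 0)          # single event at t = 3
  h <- c(0.2, -1, 0.5, 1.3)
  # subject 2 (t = 1 < 3) is outside the risk set: its score is irrelevant
  h_mod <- h; h_mod[2] <- 99
  expect_equal(cox_npll(h, time, event), cox_npll(h_mod, time, event))
  # risk set {1, 3, 4}
  expect_equal(cox_npll(h, time, event),
               -(h[3] - log(sum(exp(h[c(1, 3, 4)])))))
})

test_that("hazard training recovers risk ranking on a synthetic cohort", {
  co <- simulate_cohort(synthetic_spec(n = 800, beta = c(1, -1, 0.5, 0, 0),
                                       censor_rate = 0.3, seed = 13))
  split <- kfold_split(800, 5, seed = 2)
  train <- subset_dataset(co$dataset, split$assignments != 1)
  test <- subset_dataset(co$dataset, split$assignments == 1)
  model <- train_hazard(train, fast_spec(seed = 6))
  h <- predict_log_risk(model, test)
  lp <- co$truth$linear_predictor[split$assignments == 1]
  expect_gt(cor(h, lp, method = "spearman"), 0.7)

  # smoothed training-loss trace decreases
  tr <- model$trace$train_loss
  sm <- smoothed(tr)
  sm <- sm[!is.na(sm)]
  expect_lt(sm[length(sm)], sm[1])
})

test_that("a linear (no hidden layer) fit matches a textbook Cox model", {
  co <- simulate_cohort(synthetic_spec(n = 600, beta = c(1.5, -1.5, 0),
                                       censor_rate = 0.2, seed = 9))
  spec <- network_spec(layer_widths = 1, learning_rate = 1e-2, epochs = 1500,
                       patience = 200, dropout_rate = 0, seed = 3)
  model <- train_hazard(co$dataset, spec)
  w <- unname(drop(model$net$W[[1]]))
  cox <- survival::coxph(
    survival::Surv(co$dataset$time, co$dataset$event) ~ co$dataset$covariates)
  beta_hat <- unname(coef(cox))
  expect_equal(sign(w[1:2]), sign(beta_hat[1:2]))
  expect_equal(sign(w[1:2]), c(1, -1))
  expect_lt(max(abs(w[1:2] - beta_hat[1:2])), 0.5)
})

test_that("log-risk prediction is a deterministic row-wise map", {
  model <- train_hazard(
    simulate_cohort(synthetic_spec(n = 120, seed = 3))$dataset,
    fast_spec(layer_widths = c(8, 1), epochs = 50))
  X <- matrix(runif(50), 10, 5)
  h <- predict_log_risk(model, X)
  expect_identical(predict_log_risk(model, X), h)
  expect_equal(predict_log_risk(model, X[c(1, 1, 2), ]), h[c(1, 1, 2)])
  perm <- c(4, 2, 9, 1)
  expect_equal(predict_log_risk(model, X[perm, ]), h[perm])
  expect_error(predict_log_risk(model, X[, 1:3]), "feature")

  zero <- constant_hazard_model(p = 5, value = 0)
  expect_equal(predict_log_risk(zero, X), rep(0, 10))
})

test_that("non-finite training loss aborts with a diagnostic", {
  co <- simulate_cohort(synthetic_spec(n = 60, seed = 1))
  bad <- network_spec(layer_widths = c(8, 1), learning_rate = 1e8,
                      epochs = 30, val_fraction = 0, dropout_rate = 0)
  expect_error(train_hazard(co$dataset, bad), "non-finite|learning rate")
})
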
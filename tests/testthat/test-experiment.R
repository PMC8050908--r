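test_that("an oracle method attains IoU 1 and RMSE 0 without censoring", {
  co <- simulate_cohort(synthetic_spec(n = 200, censor_rate = 0, seed = 6))
  rep <- run_cv_experiment(co$dataset, methods = "oracle", k = 5, seed = 2,
                           hazard_spec = fast_spec(layer_widths = c(8, 1),
                                                   epochs = 30))
  expect_equal(rep$aggregate$iou, 1, tolerance = 1e-12)
  expect_equal(rep$aggregate$rmse, 0)
})

test_that("report aggregates equal independently recomputed fold means", {
  co <- simulate_cohort(synthetic_spec(n = 250, seed = 14))
  rep <- run_cv_experiment(co$dataset,
                           methods = c("exponential", "weibull"),
                           k = 3, seed = 4,
                           hazard_spec = fast_spec(layer_widths = c(8, 1),
                                                   epochs = 60))
  for (m in unique(rep$per_fold$method)) {
    rows <- rep$per_fold[rep$per_fold$method == m, ]
    agg <- rep$aggregate[rep$aggregate$method == m, ]
    expect_equal(agg$iou, mean(rows$iou))
    expect_equal(agg$rmse, mean(rows$rmse))
    expect_equal(agg$ccc, mean(rows$ccc))
  }
  path <- withr::local_tempfile(fileext = ".json")
  write_report_json(rep, path)
  parsed <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(parsed$aggregate$iou, rep$aggregate$iou)
})

test_that("the experiment is bit-reproducible under a fixed seed", {
  co <- simulate_cohort(synthetic_spec(n = 200, seed = 20))
  spec <- fast_spec(layer_widths = c(8, 1), epochs = 60)
  r1 <- run_cv_experiment(co$dataset, methods = c("proposed", "exponential"),
                          k = 3, seed = 5, hazard_spec = spec,
                          dist_spec = spec)
  r2 <- run_cv_experiment(co$dataset, methods = c("proposed", "exponential"),
                          k = 3, seed = 5, hazard_spec = spec,
                          dist_spec = spec)
  expect_identical(r1, r2)
})

test_that("grid search enumerates the grid and returns the argmin", {
  co <- simulate_cohort(synthetic_spec(n = 200, seed = 30))
  base <- fast_spec(epochs = 40)

  single <- grid_search_spec(num_hidden_layers = 2, hidden_layer_size = 8,
                             activation = "relu", dropout_rate = 0)
  res <- grid_search(co$dataset, single, target = "hazard",
                     base_spec = base, seed = 1)
  expect_equal(nrow(res$table), 1L)
  expect_equal(res$best_spec$layer_widths, c(8L, 8L, 1L))

  grid <- grid_search_spec(num_hidden_layers = 2, hidden_layer_size = c(8, 16),
                           activation = c("relu", "tanh"),
                           dropout_rate = c(0, 0.5))
  res2 <- grid_search(co$dataset, grid, target = "hazard",
                      base_spec = base, seed = 2)
  expect_equal(nrow(res2$table), 2L * 2L * 2L)
  expect_equal(res2$best_score, min(res2$table$score))
  winner <- which.min(res2$table$score)
  expect_equal(res2$best_spec$dropout_rate, res2$table$dropout_rate[winner])

  expect_error(grid_search_spec(num_hidden_layers = integer(0)), "nonempty")
})

test_that("grid search can tune the distribution network", {
  co <- simulate_cohort(synthetic_spec(n = 200, seed = 33))
  hazard <- train_hazard(co$dataset, fast_spec(layer_widths = c(8, 1),
                                               epochs = 60))
  grid <- grid_search_spec(num_hidden_layers = 2, hidden_layer_size = 8,
                           activation = "relu", dropout_rate = c(0, 0.3))
  res <- grid_search(co$dataset, grid, target = "dist", hazard = hazard,
                     base_spec = fast_spec(epochs = 40), seed = 3)
  expect_equal(nrow(res$table), 2L)
  expect_true(is.finite(res$best_score))
  expect_error(grid_search(co$dataset, grid, target = "dist"), "hazard")
})

test_that("folds without events are skipped with a warning", {
  # 3 events among 30 subjects: some folds will hold all their events
  set.seed(2)
  d <- survival_dataset(matrix(runif(60), 30, 2), time = rexp(30) + 0.5,
                        event = c(rep(1, 3), rep(0, 27)))
  ws <- testthat::capture_warnings(
    rep <- run_cv_experiment(d, methods = "exponential", k = 10, seed = 1,
                             hazard_spec = fast_spec(layer_widths = c(4, 1),
                                                     epochs = 20,
                                                     val_fraction = 0)))
  expect_true(length(ws) >= 1 && all(grepl("skipped", ws)))
  expect_lt(length(unique(rep$per_fold$fold)), 10)
})

test_that("models round-trip through single-file serialization", {
  co <- simulate_cohort(synthetic_spec(n = 150, seed = 40))
  hazard <- train_hazard(co$dataset, fast_spec(layer_widths = c(8, 1),
                                               epochs = 50))
  model <- train_distribution_net(co$dataset, hazard,
                                  fast_spec(layer_widths = c(8, 1),
                                            epochs = 50))
  path <- withr::local_tempfile(fileext = ".rds")
  write_model(model, path)
  restored <- read_model(path)
  expect_identical(predict_survival_time(restored, co$dataset),
                   predict_survival_time(model, co$dataset))
})
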
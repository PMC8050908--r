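#' Cross-validated head-to-head evaluation
#'
#' For each fold: train the hazard network on the training portion, then
#' (a) train the distribution network and predict test-set survival
#' times ("proposed"), and (b) fit each requested fixed distribution on
#' the training fold and generate test-set times from it.  Each method's
#' predicted times are compared with the held-out ground truth by
#' Kaplan-Meier curve IoU (predicted times enter their KM curve as fully
#' observed events, since the model emits times, not censoring; the
#' ground-truth curve keeps the real censoring flags), plus RMSE and
#' Lin's CCC restricted to uncensored test subjects (a censored time is
#' not a ground-truth death time).
#'
#' @param dataset a [survival_dataset()].
#' @param methods any of `"proposed"`, `"exponential"`, `"weibull"`,
#'   `"gompertz"`, and `"oracle"` (predicts the observed times — an
#'   upper bound used for harness checks).
#' @param k number of folds.
#' @param seed master seed; fold assignment and all per-fold training
#'   seeds derive from it.
#' @param hazard_spec,dist_spec [network_spec()]s for the two networks.
#' @param dx rectangle width for the IoU.
#' @param include_censored passed to [train_distribution_net()].
#' @return An object of class `evaluation_report` with `per_fold` (one
#'   row per method and fold: `iou`, `rmse`, `ccc`) and `aggregate`
#'   (per-method means).  Folds with no test events are skipped with a
#'   warning.
#' @export
run_cv_experiment <- function(dataset,
                              methods = c("proposed", "exponential",
                                          "weibull", "gompertz"),
                              k = 5, seed = 1,
                              hazard_spec = network_spec(),
                              dist_spec = network_spec(),
                              dx = 0.1,
                              include_censored = FALSE) {
  stopifnot(inherits(dataset, "survival_dataset"), length(methods) >= 1)
  known <- c("proposed", "exponential", "weibull", "gompertz", "oracle")
  if (!all(methods %in% known)) {
    stopf("unknown method(s): %s", paste(setdiff(methods, known), collapse = ", "))
  }
  n <- length(dataset$time)
  seeds <- derive_seeds(seed, 3 * k + 1)
  folds <- kfold_split(n, k, seed = seeds[1])

  rows <- list()
  for (fold in seq_len(k)) {
    test_idx <- which(folds$assignments == fold)
    train <- subset_dataset(dataset, -test_idx)
    test <- subset_dataset(dataset, test_idx)
    if (!any(test$event == 1) || !any(train$event == 1)) {
      warning(sprintf("fold %d has no events; skipped", fold))
      next
    }
    hs <- hazard_spec; hs$seed <- seeds[3 * fold - 1]
    hazard <- train_hazard(train, hs)
    h_train <- predict_log_risk(hazard, train)
    h_test <- predict_log_risk(hazard, test)
    truth_curve <- kaplan_meier(test)

    for (m in methods) {
      pred <- switch(m,
        proposed = {
          ds <- dist_spec; ds$seed <- seeds[3 * fold]
          model <- train_distribution_net(train, hazard, ds,
                                          include_censored = include_censored)
          predict_survival_time(model, test)
        },
        oracle = test$time,
        {
          cfg <- fit_distribution_params(train, family = m,
                                         log_risks = h_train,
                                         seed = seeds[3 * fold + 1])
          generate_times(cfg, h_test)
        })
      pred_curve <- kaplan_meier(pred, rep(1, length(pred)))
      ev <- test$event == 1
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, fold = fold,
        iou = curve_iou(pred_curve, truth_curve, dx = dx),
        rmse = rmse(pred[ev], test$time[ev]),
        ccc = tryCatch(ccc(pred[ev], test$time[ev]),
                       error = function(e) NA_real_))
    }
  }
  if (!length(rows)) stopf("no usable folds")
  per_fold <- do.call(rbind, rows)
  aggregate <- stats::aggregate(per_fold[c("iou", "rmse", "ccc")],
                                by = list(method = per_fold$method), mean)
  structure(list(per_fold = per_fold, aggregate = aggregate,
                 k = k, seed = seed, methods = methods),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: %d-fold CV, seed %d\n", x$k, x$seed))
  print(x$aggregate, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report an [run_cv_experiment()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(
    list(k = report$k, seed = report$seed,
         per_fold = report$per_fold, aggregate = report$aggregate),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Specify a hyperparameter grid
#'
#' Defaults cover depths 2-7, hidden sizes 8-64 (discretized to powers of
#' two), the three standard activations, and dropout 0-0.9 (discretized);
#' the continuous ranges have no stated step, so the discretizations are
#' part of this package's protocol.
#'
#' @param num_hidden_layers integer vector of depths.
#' @param hidden_layer_size integer vector of widths (all hidden layers
#'   share a width).
#' @param activation character vector of activation tags.
#' @param dropout_rate numeric vector of dropout probabilities.
#' @return An object of class `grid_search_spec`.
#' @export
grid_search_spec <- function(num_hidden_layers = 2:7,
                             hidden_layer_size = c(8, 16, 32, 64),
                             activation = c("sigmoid", "relu", "tanh"),
                             dropout_rate = c(0, 0.3, 0.5, 0.7, 0.9)) {
  if (!length(num_hidden_layers) || !length(hidden_layer_size) ||
      !length(activation) || !length(dropout_rate)) {
    stopf("every grid dimension must be nonempty")
  }
  structure(list(num_hidden_layers = as.integer(num_hidden_layers),
                 hidden_layer_size = as.integer(hidden_layer_size),
                 activation = activation,
                 dropout_rate = as.numeric(dropout_rate)),
            class = "grid_search_spec")
}

#' Exhaustive grid search over network hyperparameters
#'
#' Trains one network per grid point and scores it by the best validation
#' loss of its own objective (Cox partial likelihood for the hazard
#' network, the hazard-rescaled MSE for the distribution network); the
#' argmin configuration wins, ties broken by grid order.
#'
#' @param dataset a [survival_dataset()].
#' @param grid a [grid_search_spec()].
#' @param target `"hazard"` or `"dist"`; `"dist"` requires `hazard`.
#' @param hazard trained hazard model (for `target = "dist"`).
#' @param base_spec [network_spec()] supplying the training schedule
#'   (learning rate, epochs, validation fraction > 0, ...).
#' @param seed master seed; each grid point trains under a derived seed.
#' @return A list with `best_spec` (the winning [network_spec()]),
#'   `best_score`, and `table` (one row per configuration with its
#'   validation score).
#' @export
grid_search <- function(dataset, grid = grid_search_spec(),
                        target = c("hazard", "dist"), hazard = NULL,
                        base_spec = network_spec(), seed = 1) {
  target <- match.arg(target)
  stopifnot(inherits(grid, "grid_search_spec"))
  if (target == "dist" && !inherits(hazard, "hazard_model")) {
    stopf("target 'dist' requires a trained hazard model")
  }
  if (base_spec$val_fraction <= 0) {
    stopf("grid search needs a validation split (val_fraction > 0)")
  }
  combos <- expand.grid(num_hidden_layers = grid$num_hidden_layers,
                        hidden_layer_size = grid$hidden_layer_size,
                        activation = grid$activation,
                        dropout_rate = grid$dropout_rate,
                        stringsAsFactors = FALSE)
  seeds <- derive_seeds(seed, nrow(combos))
  scores <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    cfg <- combos[i, ]
    sp <- base_spec
    sp$layer_widths <- c(rep(cfg$hidden_layer_size, cfg$num_hidden_layers), 1L)
    sp$activation <- rep(cfg$activation, cfg$num_hidden_layers)
    sp$dropout_rate <- cfg$dropout_rate
    sp$seed <- seeds[i]
    scores[i] <- tryCatch({
      fit <- if (target == "hazard") {
        train_hazard(dataset, sp)
      } else {
        train_distribution_net(dataset, hazard, sp)
      }
      with_val <- fit$trace$val_loss[!is.na(fit$trace$val_loss)]
      if (length(with_val)) min(with_val) else min(fit$trace$train_loss)
    }, error = function(e) Inf)
  }
  best <- which.min(scores)
  best_spec <- base_spec
  best_spec$layer_widths <- c(rep(combos$hidden_layer_size[best],
                                  combos$num_hidden_layers[best]), 1L)
  best_spec$activation <- rep(combos$activation[best],
                              combos$num_hidden_layers[best])
  best_spec$dropout_rate <- combos$dropout_rate[best]
  best_spec$seed <- seeds[best]
  list(best_spec = best_spec, best_score = scores[best],
       table = cbind(combos, score = scores))
}

#' Run the full synthetic pipeline
#'
#' Simulate a censored cohort, run the cross-validated head-to-head
#' evaluation, train a final model on the full cohort and compute its
#' Grad-CAM attributions.  Fully seeded: the same arguments always
#' produce an identical result object.
#'
#' @param sim_spec a [synthetic_spec()].
#' @param hazard_spec,dist_spec [network_spec()]s.
#' @param methods methods for [run_cv_experiment()].
#' @param k folds.
#' @param seed master seed for the evaluation and final training.
#' @return A list of class `pipeline_result` with `cohort`, `report`,
#'   `final_model`, `attribution`.
#' @export
run_all <- function(sim_spec = synthetic_spec(),
                    hazard_spec = network_spec(),
                    dist_spec = network_spec(),
                    methods = c("proposed", "exponential", "weibull",
                                "gompertz"),
                    k = 5, seed = 1) {
  cohort <- simulate_cohort(sim_spec)
  report <- run_cv_experiment(cohort$dataset, methods = methods, k = k,
                              seed = seed, hazard_spec = hazard_spec,
                              dist_spec = dist_spec)
  seeds <- derive_seeds(seed + 1L, 2)
  hs <- hazard_spec; hs$seed <- seeds[1]
  ds <- dist_spec; ds$seed <- seeds[2]
  hazard <- train_hazard(cohort$dataset, hs)
  final_model <- train_distribution_net(cohort$dataset, hazard, ds)
  attribution <- gradcam_1d(final_model, cohort$dataset)
  structure(list(cohort = cohort, report = report,
                 final_model = final_model, attribution = attribution),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$report)
  cat("\nTop features by mean Grad-CAM importance:\n")
  print(round(sort(x$attribution$per_feature_mean, decreasing = TRUE), 4))
  invisible(x)
}

#' Save / load a trained model
#'
#' Single-file serialization (RDS) of a `hazard_model` or
#' `survival_time_model`, spec and weights included.
#'
#' @param model the model object.
#' @param path file path.
#' @return `path` invisibly / the restored model.
#' @export
write_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) readRDS(path)
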
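#' Hazard-rescaled squared-error loss of the distribution network
#'
#' The training objective of the distribution-function network: the mean
#' over subjects of `(y_true - y_pred / exp(h))^2`, where `y_pred` is the
#' network's raw distribution estimate and `h` the (frozen) log-risk.
#' Dividing the distribution output by the hazard ratio turns the
#' classical survival-time generator `T = u / exp(h)` into a learnable
#' regression target, so the loss is an MSE in which the prediction is
#' rescaled per subject by its hazard ratio.
#'
#' @param y_pred raw distribution-network outputs.
#' @param y_true_time observed (uncensored) survival times.
#' @param log_risks log-risk scores `h`; clipped at +/-50 before
#'   exponentiation.
#' @return The scalar mean loss.
#' @examples
#' dist_loss(5, 10, 0)        # (10 - 5)^2 = 25
#' dist_loss(10, 10, log(2))  # (10 - 5)^2 = 25
#' @export
dist_loss <- function(y_pred, y_true_time, log_risks) {
  n <- length(y_true_time)
  if (length(y_pred) != n || length(log_risks) != n) {
    stopf("y_pred, y_true_time and log_risks must align")
  }
  hr <- exp(clip_log_risk(log_risks))
  mean((y_true_time - y_pred / hr)^2)
}

#' Train the distribution-function network against a frozen hazard model
#'
#' The hazard network is pre-trained and stays frozen: only the
#' distribution network's weights move.  The raw output passes through a
#' softplus so predicted times are strictly positive, and targets are
#' internally standardized by the mean hazard-rescaled training time so
#' Adam sees a unit-scale problem regardless of the study's time units
#' (the reported loss is on the original scale).
#'
#' Censored subjects are excluded from the loss by default: a censored
#' time is only a lower bound on the survival time, so squared error
#' against it would bias predictions downward.  Set
#' `include_censored = TRUE` to treat censored times as events (ablation
#' only).
#'
#' @param dataset a [survival_dataset()]; must contain uncensored
#'   subjects (unless `include_censored = TRUE`).
#' @param hazard a trained [train_hazard()] model on the same features.
#' @param spec a [network_spec()] for the distribution network.
#' @param include_censored include censored subjects in the loss as if
#'   their censoring times were event times.
#' @return An object of class `survival_time_model` with elements
#'   `hazard` (the frozen model, byte-identical to the input), `net`,
#'   `spec`, `scale`, `trace`, `best_epoch`.
#' @export
train_distribution_net <- function(dataset, hazard, spec = network_spec(),
                                   include_censored = FALSE) {
  stopifnot(inherits(dataset, "survival_dataset"),
            inherits(hazard, "hazard_model"),
            inherits(spec, "network_spec"))
  keep <- if (include_censored) rep(TRUE, length(dataset$event)) else
    dataset$event == 1
  if (!any(keep)) {
    stopf("no uncensored subjects to train the distribution network on")
  }
  X <- dataset$covariates[keep, , drop = FALSE]
  y <- dataset$time[keep]
  h <- clip_log_risk(predict_log_risk(hazard, X))
  hr <- exp(h)

  # unit-scale standardization of the distribution targets u = y * hr
  scale <- mean(y * hr)
  y_s <- y / scale

  loss_grad <- function(out, idx) {
    # out is the pre-softplus linear output on the standardized scale
    y_pred <- softplus(out)
    r <- y_pred / hr[idx]
    resid <- y_s[idx] - r
    loss <- mean(resid^2) * scale^2
    grad <- (-2 * resid / hr[idx]) * softplus_grad(out) / length(idx) * scale^2
    list(loss = loss, grad = grad)
  }
  fit <- fit_mlp(X, spec, loss_grad, stratify = NULL)
  structure(
    list(hazard = hazard, net = fit$net, spec = spec, scale = scale,
         feature_names = dataset$feature_names,
         include_censored = include_censored,
         trace = fit$trace, best_epoch = fit$best_epoch),
    class = "survival_time_model"
  )
}

#' @export
print.survival_time_model <- function(x, ...) {
  cat(sprintf(
    "survival_time_model: dist net %s over a frozen hazard net %s\n",
    paste(x$net$widths, collapse = "-"),
    paste(x$hazard$net$widths, collapse = "-")))
  invisible(x)
}

# Raw distribution-network output y_pred (positive, original time scale).
predict_y_pred <- function(model, covariates) {
  stopifnot(inherits(model, "survival_time_model"))
  X <- covariate_matrix(model$hazard, covariates)
  softplus(mlp_forward(model$net, X)$out) * model$scale
}

#' Predict individual survival times
#'
#' The survival-time generator: `y_hat = y_pred / exp(h)` per subject,
#' with `y_pred` the distribution network's (positive) output and `h` the
#' frozen hazard network's log-risk.  Deterministic at inference.
#'
#' @param model a [train_distribution_net()] model.
#' @param covariates matrix (or `survival_dataset`) with the training
#'   feature dimension.
#' @return Strictly positive predicted survival times, one per row.
#' @export
predict_survival_time <- function(model, covariates) {
  stopifnot(inherits(model, "survival_time_model"))
  y_pred <- predict_y_pred(model, covariates)
  h <- clip_log_risk(predict_log_risk(model$hazard, covariates))
  as.numeric(y_pred / exp(h))
}

#' Histogram of distribution-network outputs across a cohort
#'
#' Bins either the raw distribution estimates `y_pred` or the final
#' predicted survival times, for inspecting the learned distribution's
#' shape.
#'
#' @param model a [train_distribution_net()] model.
#' @param covariates cohort covariates.
#' @param bins number of equal-width bins covering `[min, max]` of the
#'   outputs.
#' @param which `"y_pred"` (raw distribution output) or `"time"`
#'   (predicted survival time).
#' @return A data frame with `bin_left`, `bin_right`, `count`; counts sum
#'   to the cohort size.
#' @export
predicted_time_histogram <- function(model, covariates, bins = 20,
                                     which = c("y_pred", "time")) {
  which <- match.arg(which)
  x <- switch(which,
              y_pred = predict_y_pred(model, covariates),
              time = predict_survival_time(model, covariates))
  if (!length(x)) stopf("empty cohort")
  r <- range(x)
  if (r[1] == r[2]) {
    edges <- c(r[1] - 0.5, r[1] + 0.5)
  } else {
    edges <- seq(r[1], r[2], length.out = bins + 1L)
  }
  counts <- tabulate(pmin(findInterval(x, edges, rightmost.closed = TRUE),
                          length(edges) - 1L),
                     nbins = length(edges) - 1L)
  data.frame(bin_left = edges[-length(edges)], bin_right = edges[-1],
             count = counts)
}
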
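#' 1D Grad-CAM feature attribution
#'
#' Adapts gradient-weighted class activation mapping to dense networks
#' over tabular features.  The first hidden layer plays the role of the
#' last convolutional layer (it is the only layer with a direct linear
#' relation to named input features): per patient, the gradient of the
#' scalar output with respect to the first-hidden-layer activations
#' weights those activations, the weighted map is rectified, and the
#' result is projected back onto input features through the absolute
#' first-layer weights.  Attributions are L1-normalized per patient
#' before averaging so every patient contributes equally to the
#' per-feature means.
#'
#' For a `survival_time_model` the explained scalar is the predicted
#' survival time, and the maps of its two subnetworks (distribution and
#' hazard) are combined via the chain rule of the time generator
#' `y_hat = y_pred / exp(h)`.  For a `hazard_model` the explained scalar
#' is the log-risk.  A model without hidden layers falls back to
#' rectified gradient-times-input, with a message.
#'
#' @param model a `hazard_model` or `survival_time_model`.
#' @param covariates cohort covariates (matrix or `survival_dataset`).
#' @return An object of class `attribution_result`:
#' \describe{
#'   \item{per_patient}{`n x p` nonnegative attribution matrix (rows sum
#'     to 1 unless all-zero).}
#'   \item{per_feature_mean}{column means of `per_patient`.}
#'   \item{sort_order}{patient permutation by descending predicted
#'     survival time (for a bare hazard model, by ascending risk).}
#'   \item{predicted}{the explained scalar per patient.}
#' }
#' @export
gradcam_1d <- function(model, covariates) {
  UseMethod("gradcam_1d")
}

# Per-patient Grad-CAM map for one MLP: weight first-hidden-layer
# activations by d out / d a1 (scaled per patient by `upstream`, the
# derivative of the explained scalar w.r.t. this network's output),
# rectify, project through |W1|.
gradcam_mlp <- function(net, X, upstream = NULL) {
  L <- length(net$W)
  fw <- mlp_forward(net, X)
  n <- nrow(X)
  upstream <- upstream %||% rep(1, n)
  if (L == 1L) {
    message("model has no hidden layers; using rectified gradient x input")
    g <- outer(upstream, drop(net$W[[1L]]))   # d out / d x
    return(pmax(g * X, 0))
  }
  # gradient of the scalar output w.r.t. a1 (no dropout at inference)
  delta <- matrix(upstream, ncol = 1)
  for (l in rev(seq(2L, L))) {
    da <- delta %*% t(net$W[[l]])
    if (l - 1L >= 2L) {
      act <- activation_fn(net$activation[l - 1L])
      delta <- da * act$df(fw$z[[l - 1L]])
    } else {
      delta <- da                              # d out / d a1
    }
  }
  cam <- pmax(delta * fw$a[[2L]], 0)           # rectified grad-weighted map
  cam %*% t(abs(net$W[[1L]]))                  # back to input features
}

finalize_attribution <- function(per_patient, predicted, feature_names,
                                 descending_time_order) {
  rs <- rowSums(per_patient)
  per_patient <- per_patient / ifelse(rs > 0, rs, 1)
  colnames(per_patient) <- feature_names
  structure(
    list(per_patient = per_patient,
         per_feature_mean = colMeans(per_patient),
         sort_order = descending_time_order,
         predicted = predicted),
    class = "attribution_result"
  )
}

#' @rdname gradcam_1d
#' @export
gradcam_1d.hazard_model <- function(model, covariates) {
  X <- covariate_matrix(model, covariates)
  per_patient <- gradcam_mlp(model$net, X)
  h <- predict_log_risk(model, X)
  # higher risk ~ shorter survival: ascending risk stands in for
  # descending predicted time
  finalize_attribution(per_patient, h, model$feature_names,
                       order(h, seq_along(h)))
}

#' @rdname gradcam_1d
#' @export
gradcam_1d.survival_time_model <- function(model, covariates) {
  X <- covariate_matrix(model$hazard, covariates)
  h <- clip_log_risk(predict_log_risk(model$hazard, X))
  y_hat <- predict_survival_time(model, X)
  # y_hat = scale * softplus(o_d) / exp(h):
  #   d y_hat / d o_d =  scale * sigmoid(o_d) / exp(h)
  #   d y_hat / d h   = -y_hat
  o_d <- mlp_forward(model$net, X)$out
  cam_dist <- gradcam_mlp(model$net, X,
                          upstream = model$scale * softplus_grad(o_d) / exp(h))
  cam_haz <- gradcam_mlp(model$hazard$net, X, upstream = -y_hat)
  finalize_attribution(cam_dist + cam_haz, y_hat,
                       model$hazard$feature_names,
                       order(-y_hat, seq_along(y_hat)))
}

#' @export
print.attribution_result <- function(x, ...) {
  cat("attribution_result: per-feature mean importances\n")
  print(round(sort(x$per_feature_mean, decreasing = TRUE), 4))
  invisible(x)
}

#' Patient-by-feature attribution heat map table
#'
#' Rows are patients sorted by predicted survival time, descending (ties
#' broken by original index — stable sort); columns are features; values
#' are the per-patient Grad-CAM attributions.  The layout used for
#' heat-map visualizations of expression-like attribution patterns.
#'
#' @param attr an [gradcam_1d()] result.
#' @param predicted_times predicted survival time per patient; defaults
#'   to the scalar stored in `attr` when that scalar is a time.
#' @return A data frame with a `patient` index column followed by one
#'   column per feature, in sorted order.
#' @export
heatmap_table <- function(attr, predicted_times = NULL) {
  stopifnot(inherits(attr, "attribution_result"))
  n <- nrow(attr$per_patient)
  if (is.null(predicted_times)) {
    ord <- attr$sort_order
  } else {
    if (length(predicted_times) != n) {
      stopf("predicted_times must have one value per patient (%d)", n)
    }
    ord <- order(-predicted_times, seq_len(n))
  }
  out <- data.frame(patient = ord)
  out <- cbind(out, as.data.frame(attr$per_patient[ord, , drop = FALSE]))
  rownames(out) <- NULL
  out
}

#' Export per-feature mean importances as TSV
#'
#' @param attr an [gradcam_1d()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_feature_importance <- function(attr, path) {
  df <- data.frame(feature = names(attr$per_feature_mean),
                   importance = as.numeric(attr$per_feature_mean))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
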
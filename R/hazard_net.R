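#' Cox negative log partial likelihood
#'
#' The training objective of the hazard network.  For log-risk scores
#' `h_i`, observed times `T_i` and event flags `E_i`,
#' `L = sum over events i of -(h_i - log sum_{j in R(T_i)} exp(h_j))`
#' with risk set `R(T_i) = {j : T_j >= T_i}` (a subject is at risk at its
#' own event time).  Tied event times share the same risk set (Breslow
#' convention).  The inner sum is stabilized with a log-sum-exp shift.
#'
#' @param log_risks per-subject log-risk scores `h_i`.
#' @param time observed times.
#' @param event event flags (1 = event, 0 = censored).
#' @param normalize divide by the number of events (off by default: the
#'   partial likelihood is a sum).
#' @return The scalar loss.  Shift-invariant: adding a constant to all
#'   `log_risks` leaves it unchanged.
#' @examples
#' cox_npll(c(0, 0), time = c(1, 2), event = c(1, 1))  # log(2)
#' @export
cox_npll <- function(log_risks, time, event, normalize = FALSE) {
  cox_npll_grad(log_risks, time, event, normalize = normalize)$loss
}

# Loss plus analytic gradient d loss / d h_k:
#   grad_k = exp(h_k) * sum_{events i : T_i <= T_k} 1 / S_i  -  E_k
# with S_i the risk-set sum of exp(h).  Computed in one ascending sweep;
# the log-sum-exp shift cancels between exp(h_k) and S_i.
cox_npll_grad <- function(log_risks, time, event, normalize = FALSE) {
  n <- length(time)
  if (length(log_risks) != n || length(event) != n) {
    stopf("log_risks, time and event must align")
  }
  if (!any(event == 1)) stopf("Cox partial likelihood needs at least one event")
  # subjects censored before the first event belong to no risk set:
  # they contribute nothing to the loss and have zero gradient, and
  # excluding them keeps the log-sum-exp shift tied to scores that are
  # actually summed
  keep <- time >= min(time[event == 1])
  if (!all(keep)) {
    inner <- cox_npll_grad(log_risks[keep], time[keep], event[keep],
                           normalize = normalize)
    grad <- numeric(n)
    grad[keep] <- inner$grad
    return(list(loss = inner$loss, grad = grad))
  }
  ord <- order(time)
  t_s <- time[ord]
  e_s <- event[ord]
  h_s <- log_risks[ord]
  m <- max(h_s)
  w <- exp(h_s - m)

  # risk-set sums: S_k = sum_{j : t_j >= t_k} w_j, constant across ties
  cs <- cumsum(w)
  total <- cs[n]
  first_of_time <- which(!duplicated(t_s))
  # map each row to the first row sharing its time
  grp <- rep(seq_along(first_of_time),
             times = diff(c(first_of_time, n + 1L)))
  S <- total - c(0, cs)[first_of_time[grp]]

  ev <- e_s == 1
  loss <- sum(-(h_s[ev] - m) + log(S[ev]))

  # cumulative event terms A_k = sum_{events i : t_i <= t_k} 1 / S_i,
  # including events tied with t_k
  terms <- ifelse(ev, 1 / S, 0)
  ca <- cumsum(terms)
  last_of_time <- c(first_of_time[-1L] - 1L, n)
  A <- ca[last_of_time[grp]]
  grad_s <- w * A - e_s

  if (normalize) {
    k <- sum(ev)
    loss <- loss / k
    grad_s <- grad_s / k
  }
  grad <- numeric(n)
  grad[ord] <- grad_s
  list(loss = loss, grad = grad)
}

#' Train the hazard (log-risk) network
#'
#' Fits a DeepSurv-style multilayer perceptron mapping covariates to a
#' scalar log-risk by full-batch Adam on [cox_npll()] (risk sets couple
#' all rows, so gradients are computed over the whole training set).
#' Xavier initialization, dropout per the spec during training only, and
#' early stopping on a stratified validation split (events and censored
#' subjects held out proportionally).
#'
#' @param dataset a [survival_dataset()] with at least one event.
#' @param spec a [network_spec()].
#' @return An object of class `hazard_model` with elements `spec`, `net`
#'   (trained weights), `feature_names`, `trace` (per-epoch training and
#'   validation loss) and `best_epoch`.
#' @export
train_hazard <- function(dataset, spec = network_spec()) {
  stopifnot(inherits(dataset, "survival_dataset"),
            inherits(spec, "network_spec"))
  if (!any(dataset$event == 1)) {
    stopf("cannot train the hazard network without any events")
  }
  X <- dataset$covariates
  time <- dataset$time
  event <- dataset$event
  loss_grad <- function(out, idx) {
    cox_npll_grad(out, time[idx], event[idx], normalize = spec$normalize_loss)
  }
  fit <- fit_mlp(X, spec, loss_grad, stratify = event)
  structure(
    list(spec = spec, net = fit$net, feature_names = dataset$feature_names,
         trace = fit$trace, best_epoch = fit$best_epoch),
    class = "hazard_model"
  )
}

#' @export
print.hazard_model <- function(x, ...) {
  cat(sprintf("hazard_model: %s -> 1, trained %d epoch(s) (best %d)\n",
              paste(x$net$widths, collapse = "-"),
              nrow(x$trace), x$best_epoch))
  invisible(x)
}

# Coerce input to a covariate matrix checked against the model's
# training features.
covariate_matrix <- function(model, covariates) {
  if (inherits(covariates, "survival_dataset")) covariates <- covariates$covariates
  covariates <- as.matrix(covariates)
  p <- model$net$widths[1]
  if (ncol(covariates) != p) {
    stopf("model expects %d feature(s), got %d", p, ncol(covariates))
  }
  covariates
}

#' Predict log-risk scores
#'
#' Deterministic at inference (no dropout); `exp` of the returned score
#' is the hazard ratio used by the survival-time generator.
#'
#' @param model a trained [train_hazard()] model.
#' @param covariates matrix (or `survival_dataset`) with the training
#'   feature dimension.
#' @return One log-risk per row.
#' @export
predict_log_risk <- function(model, covariates) {
  stopifnot(inherits(model, "hazard_model"))
  X <- covariate_matrix(model, covariates)
  out <- mlp_forward(model$net, X)$out
  as.numeric(out)
}
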
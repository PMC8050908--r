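#' Specify a feed-forward network and its training schedule
#'
#' Both the hazard network and the distribution-function network are
#' small multilayer perceptrons described by this spec.  The default
#' architecture (hidden widths 64, 32, 32 with ReLU, scalar linear
#' output) mirrors the four-layer networks used for the clinical
#' datasets, with Xavier (Glorot uniform) initialization, dropout 0.5 on
#' the third hidden layer only, and full-batch Adam.
#'
#' The reference training schedule pairs a learning rate of `1e-5` with a
#' long (unstated) epoch budget; since full-batch Adam's parameter
#' displacement scales roughly with `learning_rate * epochs`, shorter
#' budgets should raise the learning rate proportionally (the simulation
#' studies in this package use `1e-3` with around a thousand epochs).
#'
#' @param layer_widths hidden-layer widths followed by the final width,
#'   which must be 1 (scalar output).
#' @param activation hidden activation tag: `"relu"`, `"sigmoid"` or
#'   `"tanh"`; either one tag for all hidden layers or one per layer.
#' @param dropout_rate dropout probability in `[0, 1)`.
#' @param dropout_layer index of the (single) hidden layer dropout is
#'   applied to; layers beyond the network depth mean no dropout.
#' @param learning_rate Adam step size.
#' @param epochs maximum full-batch epochs.
#' @param patience early-stopping patience in epochs on the validation
#'   loss; ignored when `val_fraction = 0`.
#' @param val_fraction fraction of training rows held out for early
#'   stopping (0 disables early stopping).
#' @param normalize_loss for the hazard network: divide the Cox loss by
#'   the number of events (off by default; the partial likelihood is a
#'   sum).
#' @param seed integer seed controlling initialization, dropout and the
#'   validation split.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(layer_widths = c(64, 32, 32, 1),
                         activation = "relu",
                         dropout_rate = 0.5,
                         dropout_layer = 3,
                         learning_rate = 1e-5,
                         epochs = 2000,
                         patience = 100,
                         val_fraction = 0.2,
                         normalize_loss = FALSE,
                         seed = 1) {
  layer_widths <- as.integer(layer_widths)
  if (!length(layer_widths) || layer_widths[length(layer_widths)] != 1) {
    stopf("layer_widths must end in 1 (scalar output)")
  }
  if (any(layer_widths < 1)) stopf("layer widths must be positive")
  n_hidden <- length(layer_widths) - 1L
  activation <- match.arg(activation, c("relu", "sigmoid", "tanh"),
                          several.ok = TRUE)
  if (length(activation) == 1) activation <- rep(activation, max(n_hidden, 1))
  if (n_hidden > 0 && length(activation) != n_hidden) {
    stopf("need one activation per hidden layer (%d)", n_hidden)
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stopf("dropout_rate must lie in [0, 1)")
  }
  stopifnot(learning_rate > 0, epochs >= 1,
            val_fraction >= 0, val_fraction < 1)
  structure(
    list(layer_widths = layer_widths, activation = activation,
         dropout_rate = dropout_rate, dropout_layer = as.integer(dropout_layer),
         learning_rate = learning_rate, epochs = as.integer(epochs),
         patience = as.integer(patience), val_fraction = val_fraction,
         normalize_loss = isTRUE(normalize_loss), seed = as.integer(seed)),
    class = "network_spec"
  )
}

# Derivatives are taken from the pre-activation z (not the stored
# activation, which may carry a dropout mask).
activation_fn <- function(tag) {
  switch(tag,
    relu    = list(f = function(z) pmax(z, 0),
                   df = function(z) (z > 0) * 1),
    sigmoid = list(f = stats::plogis,
                   df = function(z) { p <- stats::plogis(z); p * (1 - p) }),
    tanh    = list(f = tanh,
                   df = function(z) 1 - tanh(z)^2),
    stopf("unknown activation '%s'", tag))
}

# Xavier/Glorot uniform initialization; weights drawn under the RNG state
# current at the call (callers seed via with_seed).
mlp_init <- function(p, spec) {
  widths <- c(p, spec$layer_widths)
  L <- length(widths) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- widths[l]
    fan_out <- widths[l + 1L]
    limit <- sqrt(6 / (fan_in + fan_out))
    W[[l]] <- matrix(stats::runif(fan_in * fan_out, -limit, limit),
                     nrow = fan_in, ncol = fan_out)
    b[[l]] <- rep(0, fan_out)
  }
  list(W = W, b = b, widths = widths,
       activation = spec$activation,
       dropout_rate = spec$dropout_rate,
       dropout_layer = spec$dropout_layer)
}

# Forward pass.  `dropout_mask`, when non-NULL, is an n x width matrix of
# inverted-dropout multipliers for the configured hidden layer.
mlp_forward <- function(net, X, dropout_mask = NULL) {
  L <- length(net$W)
  a <- vector("list", L + 1L)
  z <- vector("list", L)
  a[[1]] <- X
  for (l in seq_len(L)) {
    z[[l]] <- sweep(a[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
    if (l < L) {
      act <- activation_fn(net$activation[l])
      a[[l + 1L]] <- act$f(z[[l]])
      if (!is.null(dropout_mask) && l == net$dropout_layer) {
        a[[l + 1L]] <- a[[l + 1L]] * dropout_mask
      }
    } else {
      a[[l + 1L]] <- z[[l]]   # linear scalar output
    }
  }
  list(a = a, z = z, out = drop(a[[L + 1L]]))
}

# Backward pass: `dout` is dLoss/d(output) per row.  Returns gradient
# lists matching net$W / net$b.
mlp_backward <- function(net, fw, dout, dropout_mask = NULL) {
  L <- length(net$W)
  dW <- vector("list", L)
  db <- vector("list", L)
  delta <- matrix(dout, ncol = 1)          # d loss / d z_L
  for (l in rev(seq_len(L))) {
    dW[[l]] <- crossprod(fw$a[[l]], delta)
    db[[l]] <- colSums(delta)
    if (l > 1) {
      da <- delta %*% t(net$W[[l]])
      if (!is.null(dropout_mask) && (l - 1L) == net$dropout_layer) {
        da <- da * dropout_mask
      }
      act <- activation_fn(net$activation[l - 1L])
      delta <- da * act$df(fw$z[[l - 1L]])
    }
  }
  list(dW = dW, db = db)
}

adam_init <- function(net) {
  zero <- function(x) lapply(x, function(m) m * 0)
  list(mW = zero(net$W), vW = zero(net$W),
       mb = zero(net$b), vb = zero(net$b), t = 0L)
}

adam_step <- function(net, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (l in seq_along(net$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$dW[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$dW[[l]]^2
    net$W[[l]] <- net$W[[l]] -
      lr * (state$mW[[l]] / c1) / (sqrt(state$vW[[l]] / c2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$db[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$db[[l]]^2
    net$b[[l]] <- net$b[[l]] -
      lr * (state$mb[[l]] / c1) / (sqrt(state$vb[[l]] / c2) + eps)
  }
  list(net = net, state = state)
}

# Shared full-batch training loop.
#
# loss_grad(out, idx) must return list(loss = scalar, grad = dLoss/dout
# over rows idx); it is called with the training rows each epoch and with
# the validation rows (no dropout) for early stopping.  `stratify` gives
# a binary label used to keep both strata represented in the validation
# split (events vs censored).
fit_mlp <- function(X, spec, loss_grad, stratify = NULL) {
  n <- nrow(X)
  with_seed(spec$seed, {
    net <- mlp_init(ncol(X), spec)
    state <- adam_init(net)

    idx_all <- seq_len(n)
    use_val <- spec$val_fraction > 0 && n >= 10
    if (use_val) {
      if (is.null(stratify)) stratify <- rep(1, n)
      val_idx <- unlist(lapply(unique(stratify), function(s) {
        grp <- idx_all[stratify == s]
        k <- floor(length(grp) * spec$val_fraction)
        if (k >= 1) sample(grp, k) else integer(0)
      }))
      if (!length(val_idx)) use_val <- FALSE
    }
    train_idx <- if (use_val) setdiff(idx_all, val_idx) else idx_all
    Xtr <- X[train_idx, , drop = FALSE]
    Xval <- if (use_val) X[val_idx, , drop = FALSE]

    drop_width <- if (spec$dropout_rate > 0 &&
                      spec$dropout_layer <= length(net$W) - 1L) {
      net$widths[spec$dropout_layer + 1L]
    } else {
      0L
    }

    trace_train <- rep(NA_real_, spec$epochs)
    trace_val <- rep(NA_real_, spec$epochs)
    best <- list(loss = Inf, net = net, epoch = 0L)
    stall <- 0L

    for (ep in seq_len(spec$epochs)) {
      mask <- if (drop_width > 0) {
        keep <- matrix(stats::runif(length(train_idx) * drop_width) >
                         spec$dropout_rate,
                       nrow = length(train_idx))
        keep / (1 - spec$dropout_rate)
      }
      fw <- mlp_forward(net, Xtr, dropout_mask = mask)
      lg <- loss_grad(fw$out, train_idx)
      if (!is.finite(lg$loss)) {
        stopf("non-finite training loss at epoch %d; lower the learning rate",
              ep)
      }
      grads <- mlp_backward(net, fw, lg$grad, dropout_mask = mask)
      upd <- adam_step(net, grads, state, spec$learning_rate)
      net <- upd$net
      state <- upd$state
      trace_train[ep] <- lg$loss

      if (use_val) {
        vout <- mlp_forward(net, Xval)$out
        vloss <- loss_grad(vout, val_idx)$loss
        trace_val[ep] <- vloss
        if (vloss < best$loss - 1e-12) {
          best <- list(loss = vloss, net = net, epoch = ep)
          stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= spec$patience) break
        }
      } else {
        best <- list(loss = lg$loss, net = net, epoch = ep)
      }
    }
    done <- !is.na(trace_train)
    list(net = best$net, best_epoch = best$epoch,
         trace = data.frame(epoch = which(done),
                            train_loss = trace_train[done],
                            val_loss = trace_val[done]))
  })
}
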
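# Independent oracles and shared fixtures for the test suite.

# Brute-force product-limit oracle, coded from the definition and
# independently of the package: walk the distinct observed times in
# order, maintain the at-risk set explicitly, and multiply the survival
# probability at every time that carries at least one event.
km_oracle <- function(time, event) {
  at_risk <- seq_along(time)
  s <- 1
  bp <- numeric(0)
  vals <- numeric(0)
  for (t in sort(unique(time))) {
    n_j <- length(at_risk)
    d_j <- sum(time[at_risk] == t & event[at_risk] == 1)
    if (d_j > 0) {
      s <- s * (1 - d_j / n_j)
      bp <- c(bp, t)
      vals <- c(vals, s)
    }
    at_risk <- at_risk[time[at_risk] != t]
  }
  list(breakpoints = bp, values = vals)
}

# Direct textbook evaluation of the Cox negative log partial likelihood
# (no log-sum-exp trick, explicit risk-set loops).
cox_npll_oracle <- function(h, time, event) {
  s <- 0
  for (i in which(event == 1)) {
    rs <- which(time >= time[i])
    s <- s - (h[i] - log(sum(exp(h[rs]))))
  }
  s
}

# Training schedule used throughout the tests: the reference lr 1e-5 is
# paired with an unstated (large) epoch budget, so desk-scale runs use an
# equivalent-displacement schedule (lr 1e-3, early stopping).
fast_spec <- function(layer_widths = c(32, 16, 16, 1), seed = 1,
                      epochs = 800, learning_rate = 1e-3, ...) {
  network_spec(layer_widths = layer_widths, seed = seed, epochs = epochs,
               learning_rate = learning_rate, patience = 100, ...)
}

# Hand-crafted constant-output model: log-risk == `value` everywhere.
constant_hazard_model <- function(p, value = 0, widths = c(4, 1)) {
  spec <- network_spec(layer_widths = widths, dropout_rate = 0)
  net <- coxdistnet:::with_seed(1, coxdistnet:::mlp_init(p, spec))
  for (l in seq_along(net$W)) {
    net$W[[l]][] <- 0
    net$b[[l]][] <- 0
  }
  net$b[[length(net$b)]] <- value
  structure(list(spec = spec, net = net,
                 feature_names = paste0("x", seq_len(p)),
                 trace = data.frame(), best_epoch = 0L),
            class = "hazard_model")
}

# Model whose log-risk is `weight * x[feature]` through one hidden relu
# unit pair (+/- paths) so gradients are informative.
single_feature_hazard_model <- function(p, feature = 1, weight = 1) {
  m <- constant_hazard_model(p, value = 0, widths = c(2, 1))
  m$net$W[[1]][feature, ] <- c(weight, -weight)
  m$net$W[[2]][] <- c(1, -1)
  m
}

# Assemble a survival_time_model with prescribed constant y_pred and
# log-risk, for unit-semantics checks of the time generator.
constant_survival_model <- function(p, y_pred, log_risk) {
  hazard <- constant_hazard_model(p, value = log_risk)
  dist <- constant_hazard_model(p, value = log(exp(y_pred) - 1))  # softplus^-1
  structure(list(hazard = hazard, net = dist$net, spec = dist$spec,
                 scale = 1, feature_names = hazard$feature_names,
                 include_censored = FALSE,
                 trace = data.frame(), best_epoch = 0L),
            class = "survival_time_model")
}

smoothed <- function(x, w = 25) stats::filter(x, rep(1 / w, w), sides = 1)
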
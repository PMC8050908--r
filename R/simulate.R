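#' Specify a synthetic censored cohort
#'
#' Describes the generative world for simulation studies: covariates
#' uniform on `[0, 1]`, a proportional-hazards event-time model
#' `h(t | x) = h0(t) * exp(beta' x)` with a parametric baseline hazard
#' `h0`, and independent exponential right-censoring calibrated to a
#' target censored fraction.
#'
#' Baseline families and their parameters (all strictly positive):
#' \describe{
#'   \item{exponential}{`rate` — constant hazard `rate`.}
#'   \item{weibull}{`shape`, `scale` — cumulative hazard `(t/scale)^shape`.}
#'   \item{gompertz}{`shape`, `rate` — hazard `rate * exp(shape * t)`.}
#' }
#'
#' @param n subject count.
#' @param beta true log-hazard coefficient vector (length = number of
#'   features).
#' @param baseline baseline family tag: `"exponential"`, `"weibull"` or
#'   `"gompertz"`.
#' @param baseline_params named list of the family's parameters.
#' @param censor_rate target censored fraction in `[0, 1)`.
#' @param seed integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n = 1000,
                           beta = c(1, -1, 0.5, 0, 0),
                           baseline = c("exponential", "weibull", "gompertz"),
                           baseline_params = NULL,
                           censor_rate = 0.3,
                           seed = 1) {
  baseline <- match.arg(baseline)
  defaults <- switch(baseline,
    exponential = list(rate = 0.1),
    weibull     = list(shape = 1.5, scale = 10),
    gompertz    = list(shape = 0.1, rate = 0.05)
  )
  baseline_params <- utils::modifyList(defaults, as.list(baseline_params %||% list()))
  required <- names(defaults)
  if (!all(required %in% names(baseline_params))) {
    stopf("baseline '%s' requires parameters: %s", baseline,
          paste(required, collapse = ", "))
  }
  if (any(unlist(baseline_params[required]) <= 0)) {
    stopf("baseline parameters must be strictly positive")
  }
  if (censor_rate < 0 || censor_rate >= 1) {
    stopf("censor_rate must lie in [0, 1)")
  }
  structure(
    list(n = as.integer(n), beta = as.numeric(beta), baseline = baseline,
         baseline_params = baseline_params[required],
         censor_rate = censor_rate, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# Inverse of the baseline cumulative hazard H0; event times follow from
# T = H0^{-1}(-log(U) / exp(beta' x)) (inverse-transform sampling under
# proportional hazards).
baseline_inv_cumhaz <- function(baseline, params, v) {
  switch(baseline,
    exponential = v / params$rate,
    weibull     = params$scale * v^(1 / params$shape),
    gompertz    = log1p(params$shape * v / params$rate) / params$shape,
    stopf("unknown baseline family '%s'", baseline)
  )
}

#' Simulate a right-censored cohort with known ground truth
#'
#' Draws covariates uniform on `[0, 1]`, event times from the spec's
#' proportional-hazards model by inverse-transform sampling, and an
#' independent exponential censoring time whose rate is solved
#' numerically so the realized censored fraction matches
#' `spec$censor_rate` in expectation.  The observed time is the minimum
#' of the two; the event flag records which one it was.
#'
#' @param spec a [synthetic_spec()].
#' @return A list of class `simulated_cohort`:
#' \describe{
#'   \item{dataset}{the observed [survival_dataset()] (covariates, time,
#'     event).}
#'   \item{truth}{hidden ground truth: `linear_predictor` (`beta' x`),
#'     `event_time` (uncensored), `censor_time`.}
#'   \item{spec}{the generating spec.}
#' }
#' @examples
#' cohort <- simulate_cohort(synthetic_spec(n = 200, seed = 7))
#' cohort$dataset
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  p <- length(spec$beta)
  with_seed(spec$seed, {
    X <- matrix(stats::runif(spec$n * p), nrow = spec$n, ncol = p)
    lp <- drop(X %*% spec$beta)
    u <- stats::runif(spec$n)
    event_time <- baseline_inv_cumhaz(spec$baseline, spec$baseline_params,
                                      -log(u) / exp(lp))
    if (spec$censor_rate == 0) {
      censor_time <- rep(Inf, spec$n)
    } else {
      # P(C < T) = E[1 - exp(-theta * T)] for C ~ Exp(theta) independent
      # of T; solve for theta on the realized event times.
      target <- spec$censor_rate
      f <- function(log_theta) mean(1 - exp(-exp(log_theta) * event_time)) - target
      log_theta <- stats::uniroot(f, interval = c(-40, 40))$root
      censor_time <- stats::rexp(spec$n, rate = exp(log_theta))
    }
    time <- pmin(event_time, censor_time)
    event <- as.numeric(event_time <= censor_time)
    dataset <- survival_dataset(X, time, event,
                                feature_names = paste0("x", seq_len(p)))
    structure(
      list(dataset = dataset,
           truth = list(linear_predictor = lp, event_time = event_time,
                        censor_time = censor_time),
           spec = spec),
      class = "simulated_cohort"
    )
  })
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("simulated_cohort (%s baseline, target censoring %.0f%%)\n",
              x$spec$baseline, 100 * x$spec$censor_rate))
  print(x$dataset)
  invisible(x)
}
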
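#' Construct a survival step curve
#'
#' A right-continuous, non-increasing step function `S(t)` with `S = 1`
#' on `[0, first breakpoint)`; the representation of Kaplan-Meier
#' estimates and the operand of the curve IoU metric.
#'
#' @param breakpoints strictly increasing positive times at which the
#'   curve drops (may be empty for the constant curve 1).
#' @param values survival probability immediately after each breakpoint;
#'   non-increasing, in `[0, 1]`.
#' @param domain_end largest time the curve is considered defined over;
#'   defaults to the last breakpoint.
#' @return An object of class `step_curve`.
#' @export
step_curve <- function(breakpoints, values, domain_end = NULL) {
  breakpoints <- as.numeric(breakpoints)
  values <- as.numeric(values)
  if (length(breakpoints) != length(values)) {
    stopf("breakpoints and values must have equal length")
  }
  if (length(breakpoints)) {
    if (any(breakpoints <= 0)) stopf("breakpoints must be strictly positive")
    if (is.unsorted(breakpoints, strictly = TRUE)) {
      stopf("breakpoints must be strictly increasing")
    }
    if (any(values < 0 | values > 1)) stopf("values must lie in [0, 1]")
    if (is.unsorted(rev(values))) stopf("values must be non-increasing")
  }
  domain_end <- domain_end %||% if (length(breakpoints)) max(breakpoints) else 1
  if (domain_end <= 0) stopf("domain_end must be positive")
  structure(list(breakpoints = breakpoints, values = values,
                 domain_end = as.numeric(domain_end)),
            class = "step_curve")
}

#' Evaluate a step curve
#'
#' @param curve a [step_curve()].
#' @param t times (vector); any `t` at or beyond the last breakpoint
#'   returns the final value (right-continuous convention).
#' @return Survival probabilities `S(t)`.
#' @export
curve_eval <- function(curve, t) {
  vals <- c(1, curve$values)
  vals[findInterval(t, curve$breakpoints) + 1L]
}

#' @export
print.step_curve <- function(x, ...) {
  cat(sprintf("step_curve: %d drop(s), domain [0, %g], final value %.4f\n",
              length(x$breakpoints), x$domain_end,
              if (length(x$values)) x$values[length(x$values)] else 1))
  invisible(x)
}

#' Kaplan-Meier product-limit estimator
#'
#' At each distinct event time `t_j` with `d_j` events among `n_j`
#' subjects at risk, the survival estimate multiplies by
#' `(1 - d_j / n_j)`; censored times only shrink the risk set.  Chosen as
#' the ground-truth curve for evaluation because it accounts for right
#' censoring.
#'
#' @param time positive observation times, or a `survival_dataset`
#'   (in which case `event` is taken from it).
#' @param event event indicators aligned with `time`.
#' @return A [step_curve()] with breakpoints at the distinct event times
#'   and `domain_end` at the largest observed time.
#' @examples
#' km <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
#' curve_eval(km, c(0.5, 1.5, 2.5, 3.5))  # 1, 2/3, 1/3, 0
#' @export
kaplan_meier <- function(time, event = NULL) {
  if (inherits(time, "survival_dataset")) {
    event <- time$event
    time <- time$time
  }
  time <- as.numeric(time)
  event <- as.numeric(event)
  if (!length(time) || length(time) != length(event)) {
    stopf("time and event must be nonempty and aligned")
  }
  if (any(time <= 0)) stopf("all times must be strictly positive")
  ord <- order(time)
  t_s <- time[ord]
  e_s <- event[ord]
  ut <- unique(t_s[e_s == 1])
  if (!length(ut)) {
    return(step_curve(numeric(0), numeric(0), domain_end = max(time)))
  }
  n <- length(t_s)
  # subjects at risk at t: observed time >= t
  n_at_risk <- vapply(ut, function(t) sum(t_s >= t), numeric(1))
  d <- vapply(ut, function(t) sum(t_s == t & e_s == 1), numeric(1))
  S <- cumprod(1 - d / n_at_risk)
  step_curve(ut, S, domain_end = max(time))
}

#' Rectangle-sum area under a survival curve
#'
#' Approximates the area under `S(t)` on `[0, t_max]` by left-endpoint
#' rectangles of width `dx` (the last rectangle is shortened so the grid
#' covers `t_max` exactly).  The approximation converges to the exact
#' step-function integral as `dx` shrinks.
#'
#' @param curve a [step_curve()].
#' @param dx rectangle width, default 0.1.
#' @param t_max upper integration limit; defaults to the curve's
#'   `domain_end`.
#' @return The nonnegative rectangle-sum area.
#' @export
curve_area <- function(curve, dx = 0.1, t_max = NULL) {
  t_max <- t_max %||% curve$domain_end
  if (t_max <= 0) stopf("t_max must be positive")
  if (dx <= 0) stopf("dx must be positive")
  g <- area_grid(t_max, dx)
  sum(curve_eval(curve, g$left) * g$width)
}

# Left endpoints and widths of the rectangle grid covering [0, t_max].
area_grid <- function(t_max, dx) {
  m <- ceiling(t_max / dx - 1e-9)
  left <- (seq_len(m) - 1) * dx
  width <- rep(dx, m)
  width[m] <- t_max - left[m]
  list(left = left, width = width)
}

#' Intersection-over-union of two survival curves
#'
#' The area under the pointwise minimum of the two curves divided by the
#' area under the pointwise maximum, both computed by the same
#' left-endpoint rectangle sum as [curve_area()].  The curves are
#' compared over `[0, t_max]` with `t_max` the larger of the two domain
#' ends; each curve extends beyond its last breakpoint at its final
#' value.  Since every survival curve starts at 1, the union area is
#' positive and the ratio is always in `[0, 1]`; identical curves give 1.
#'
#' @param pred,truth [step_curve()] objects (predicted and ground-truth
#'   curves).
#' @param dx rectangle width, default 0.1.
#' @return The IoU in `[0, 1]`.
#' @export
curve_iou <- function(pred, truth, dx = 0.1) {
  stopifnot(inherits(pred, "step_curve"), inherits(truth, "step_curve"))
  t_max <- max(pred$domain_end, truth$domain_end)
  if (t_max <= 0) stopf("curves must span a positive time range")
  g <- area_grid(t_max, dx)
  a <- curve_eval(pred, g$left)
  b <- curve_eval(truth, g$left)
  sum(pmin(a, b) * g$width) / sum(pmax(a, b) * g$width)
}

#' Root mean squared error
#'
#' @param pred,truth aligned numeric vectors.
#' @return `sqrt(mean((pred - truth)^2))`.
#' @export
rmse <- function(pred, truth) {
  if (!length(pred) || length(pred) != length(truth)) {
    stopf("pred and truth must be nonempty and of equal length")
  }
  sqrt(mean((pred - truth)^2))
}

#' Lin's concordance correlation coefficient
#'
#' Measures agreement with the 45-degree line:
#' `2 cov(pred, truth) / (var(pred) + var(truth) + (mean(pred) - mean(truth))^2)`.
#' Values near +/-1 indicate perfect (anti-)concordance; 0 indicates no
#' concordance.
#'
#' @param pred,truth aligned numeric vectors of length >= 2, each with
#'   nonzero variance.
#' @return The CCC in `[-1, 1]`.
#' @export
ccc <- function(pred, truth) {
  if (length(pred) < 2 || length(pred) != length(truth)) {
    stopf("pred and truth must be aligned with length >= 2")
  }
  v1 <- stats::var(pred)
  v2 <- stats::var(truth)
  if (v1 == 0 || v2 == 0) {
    stopf("ccc is undefined when either input has zero variance")
  }
  2 * stats::cov(pred, truth) / (v1 + v2 + (mean(pred) - mean(truth))^2)
}

#' Export a step curve as TSV
#'
#' Two columns (`time`, `survival`): the curve's value after each
#' breakpoint plus the starting point `(0, 1)`, for external plotting.
#'
#' @param curve a [step_curve()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_step_curve <- function(curve, path) {
  df <- data.frame(time = c(0, curve$breakpoints),
                   survival = c(1, curve$values))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
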
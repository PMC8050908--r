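# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  All user-facing stochastic
# operations route their randomness through this so that a seed argument
# never clobbers the session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive `m` child seeds from one parent seed; keeps every derived seed
# within 32-bit integer range.
derive_seeds <- function(seed, m) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, m))
}

# Log-risk guard before exponentiation (predicted hazard ratios): exp(50)
# already exceeds 5e21, so clipping cannot bite on any sane model while
# making exp() overflow impossible.
RISK_CLIP <- 50

clip_log_risk <- function(h, limit = RISK_CLIP) {
  pmin(pmax(h, -limit), limit)
}

softplus <- function(z) {
  # numerically stable log(1 + exp(z))
  ifelse(z > 30, z, log1p(exp(pmin(z, 30))))
}

softplus_grad <- function(z) stats::plogis(z)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
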
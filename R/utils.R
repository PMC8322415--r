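# Internal numerical helpers shared across modules.

# Largest exponent fed to exp()/10^ before clipping; keeps dose/EC50 power
# terms finite (exp(700) ~ 1e304) without changing steady-state ratios,
# because transition-matrix rows are rescaled before solving.
.EXP_CLIP <- 700

# x^p computed in log space with overflow clipping; x >= 0, p > 0.
# Returns 0 for x = 0 (p > 0 always holds for Hill exponents).
.pow_clipped <- function(x, p) {
  out <- numeric(length(x))
  pos <- x > 0
  if (any(pos)) {
    lg <- p * log(x[pos])
    lg <- pmin(pmax(lg, -.EXP_CLIP), .EXP_CLIP)
    out[pos] <- exp(lg)
  }
  out
}

# Evaluate fn() with the RNG in a reproducible, restorable state.
.with_seed <- function(seed, fn) {
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
    })
    set.seed(seed)
  }
  fn()
}

# Forward-difference Jacobian of a residual function with an absolute step
# floor. The default MINPACK step is proportional to |par|, which freezes
# any parameter whose current value is near zero — a routine occurrence for
# log10-scale parameters — so we always step at least `h_min`.
.num_jac <- function(fn, par, ..., h_min = 1e-7) {
  r0 <- fn(par, ...)
  out <- matrix(0, nrow = length(r0), ncol = length(par))
  for (j in seq_along(par)) {
    h <- h_min * max(1, abs(par[j]))
    pj <- par
    pj[j] <- pj[j] + h
    out[, j] <- (fn(pj, ...) - r0) / h
  }
  out
}

.stopifnot_scalar_number <- function(x, name, positive = FALSE,
                                     nonnegative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  if (nonnegative && x < 0) {
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  }
  invisible(x)
}

.check_doses <- function(d, name = "d") {
  if (!is.numeric(d) || length(d) == 0L) {
    stop(sprintf("`%s` must be numeric", name), call. = FALSE)
  }
  if (any(!is.finite(d)) || any(d < 0)) {
    stop(sprintf("`%s` must be finite and >= 0", name), call. = FALSE)
  }
  invisible(d)
}
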
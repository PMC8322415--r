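#' Single-drug Hill parameters
#'
#' Bundles the four parameters of the sigmoidal (Hill) dose-response curve of
#' one drug in isolation: the baseline effect `e0` at zero dose, the plateau
#' effect `emax` at saturating dose, the EC50 `ec50` (the dose producing the
#' half-maximal effect change) and the Hill slope `hill` controlling the
#' steepness of the transition. In the mass-action view the EC50 is
#' `(r_rev / r_fwd)^(1/h)`, the dose at which the affected and unaffected
#' populations are equal.
#'
#' @param e0 Effect at zero dose (assay units).
#' @param emax Effect at saturating dose (assay units). For viability-like
#'   (decreasing) readouts `emax < e0`.
#' @param ec50 EC50, strictly positive, in the caller's concentration units.
#' @param hill Hill slope, strictly positive, dimensionless.
#' @return An object of class `hill_params`.
#' @examples
#' p <- hill_params(e0 = 1, emax = 0, ec50 = 1, hill = 2)
#' hill_1d(c(0, 1, 2), p)
#' @export
hill_params <- function(e0, emax, ec50, hill) {
  .stopifnot_scalar_number(e0, "e0")
  .stopifnot_scalar_number(emax, "emax")
  .stopifnot_scalar_number(ec50, "ec50", positive = TRUE)
  .stopifnot_scalar_number(hill, "hill", positive = TRUE)
  structure(
    list(e0 = e0, emax = emax, ec50 = ec50, hill = hill),
    class = "hill_params"
  )
}

#' @export
print.hill_params <- function(x, ...) {
  cat(sprintf(
    "Hill dose-response parameters\n  E0 = %g, Emax = %g, EC50 = %g, h = %g\n",
    x$e0, x$emax, x$ec50, x$hill
  ))
  invisible(x)
}

#' Four-parameter Hill dose-response curve
#'
#' Evaluates `E(d) = Emax + (E0 - Emax) / (1 + (d/C)^h)`. The curve is
#' continuous and strictly monotone in `d` whenever `E0 != Emax`, passes
#' through `E0` at `d = 0`, through the midpoint `(E0 + Emax)/2` at `d = C`,
#' and approaches `Emax` as `d` grows.
#'
#' @param d Vector of doses, finite and non-negative.
#' @param p A [hill_params()] object.
#' @return Effect values, same length as `d`.
#' @seealso [hill_1d_inverse()]
#' @export
hill_1d <- function(d, p) {
  stopifnot(inherits(p, "hill_params"))
  .check_doses(d)
  p$emax + (p$e0 - p$emax) / (1 + .pow_clipped(d / p$ec50, p$hill))
}

#' Inverse Hill curve: dose producing a given effect
#'
#' Solves the four-parameter Hill equation for dose:
#' `d = C * ((E0 - Emax)/(E - Emax) - 1)^(1/h)`. The inverse is defined only
#' for effects strictly between the baseline and the plateau; effects at or
#' beyond either bound return `NA` (the "undefined" signal consumed by the
#' Loewe and combination-index calculations, which must drop such points).
#'
#' @param E Vector of effect values.
#' @param p A [hill_params()] object.
#' @return Doses; `NA` where `E` is outside the open effect range.
#' @export
hill_1d_inverse <- function(E, p) {
  stopifnot(inherits(p, "hill_params"))
  lo <- min(p$e0, p$emax)
  hi <- max(p$e0, p$emax)
  out <- rep(NA_real_, length(E))
  ok <- is.finite(E) & E > lo & E < hi
  if (any(ok)) {
    ratio <- (p$e0 - p$emax) / (E[ok] - p$emax) - 1
    out[ok] <- p$ec50 * ratio^(1 / p$hill)
  }
  out
}

#' Fit the four-parameter Hill equation to monotherapy data
#'
#' Bounded nonlinear least squares of the Hill curve to (dose, effect) pairs.
#' Internally the EC50 and Hill slope are parameterized as log10 values to
#' mitigate the strong slope/EC50 collinearity of the Hill equation (visible
#' in its log-linearized form, where the intercept is `-h log C`); reported
#' estimates are back-transformed. Initial guesses are deterministic: the
#' median effect at the lowest and highest dose for `E0`/`Emax`, the
#' geometric-mean positive dose for `C`, and `h = 1`.
#'
#' Fits are rejected (with `converged = FALSE` and a reason) when the
#' optimizer fails, or when the fitted curve is flat, i.e.
#' `|E0 - Emax|` is below 1% of the observed effect range.
#'
#' @param d,effect Numeric vectors of doses (>= 0) and measured effects.
#' @param e0_bounds,emax_bounds Length-2 numeric bounds on the baseline and
#'   plateau effects (default unbounded). EC50 and slope are effectively
#'   unconstrained (wide log10 bounds).
#' @return A list of class `hill_fit` with elements `params`
#'   ([hill_params()] or `NULL`), `theta`/`se` (estimates and standard errors
#'   in the internal `(E0, Emax, log10 C, log10 h)` parameterization),
#'   `converged`, `reason`, `rss`.
#' @export
fit_hill_1d <- function(d, effect, e0_bounds = c(-Inf, Inf),
                        emax_bounds = c(-Inf, Inf)) {
  .check_doses(d)
  stopifnot(is.numeric(effect), length(effect) == length(d))
  fail <- function(reason) {
    structure(
      list(params = NULL, theta = NULL, se = NULL, converged = FALSE,
           reason = reason, rss = NA_real_),
      class = "hill_fit"
    )
  }
  if (any(!is.finite(effect))) return(fail("non-finite effects"))
  if (length(unique(d)) < 4L) return(fail("fewer than 4 distinct doses"))
  rng <- diff(range(effect))
  if (rng <= 0) return(fail("constant effect values"))

  dpos <- d[d > 0]
  lc0 <- mean(log10(dpos))
  th0 <- c(
    e0 = stats::median(effect[d == min(d)]),
    emax = stats::median(effect[d == max(d)]),
    lc = lc0,
    lh = 0
  )
  lower <- c(e0_bounds[1], emax_bounds[1], log10(min(dpos)) - 6, -3)
  upper <- c(e0_bounds[2], emax_bounds[2], log10(max(dpos)) + 6, 3)
  th0 <- pmin(pmax(th0, lower), upper)

  resid_fn <- function(th) {
    effect - (th[2] + (th[1] - th[2]) /
                (1 + .pow_clipped(d / 10^th[3], 10^th[4])))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = th0, lower = lower, upper = upper, fn = resid_fn,
      jac = function(th) .num_jac(resid_fn, th),
      control = minpack.lm::nls.lm.control(
        maxiter = 500, ftol = 1e-15, ptol = 1e-15
      )
    ),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$info %in% 1:4) return(fail("optimizer failure"))
  th <- fit$par
  if (abs(th[1] - th[2]) < 0.01 * rng) return(fail("flat dose-response"))

  # standard errors from the Gauss-Newton covariance; Inf where the
  # Jacobian is (numerically) rank deficient, which downstream bound
  # propagation treats as "no information".
  dof <- max(length(d) - 4L, 1L)
  sigma2 <- sum(fit$fvec^2) / dof
  se <- tryCatch({
    cov <- sigma2 * solve(fit$hessian)
    sqrt(pmax(diag(cov), 0))
  }, error = function(e) rep(Inf, 4L))
  names(se) <- names(th) <- c("e0", "emax", "lc", "lh")

  structure(
    list(
      params = hill_params(th[["e0"]], th[["emax"]], 10^th[["lc"]],
                           10^th[["lh"]]),
      theta = th, se = se, converged = TRUE, reason = NULL,
      rss = sum(fit$fvec^2)
    ),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Hill fit: FAILED (", x$reason, ")\n", sep = "")
  } else {
    cat("Hill fit (converged):\n")
    print(x$params)
  }
  invisible(x)
}

#' Median-effect (two-parameter Hill) fit
#'
#' The Chou-Talalay median-effect equation is the Hill curve specialized to
#' `E0 = 1`, `Emax = 0`, log-linearized as
#' `log((1/E) - 1) = h log d - h log C` and fitted by ordinary linear
#' regression, mirroring the CompuSyn procedure. Points with effect >= 1 are
#' excluded (the left side becomes complex), as are points with effect <= 0
#' or zero dose (log undefined). The fit is flagged undefined when fewer
#' than two usable points remain or when the fitted slope is negative (a
#' physically unrealistic Hill slope).
#'
#' This estimator is exact when the data truly have `E0 = 1, Emax = 0`; for
#' partially efficacious drugs (`Emax > 0`) it is systematically biased,
#' which is one source of the combination index's effect-range bias.
#'
#' @param d,effect Doses and effects (effects interpreted as fraction
#'   unaffected).
#' @return A list of class `median_effect_fit` with `ec50`, `hill`,
#'   `defined`, `reason`, `n_used`.
#' @export
median_effect_fit <- function(d, effect) {
  stopifnot(is.numeric(d), is.numeric(effect), length(d) == length(effect))
  undef <- function(reason, n_used = 0L) {
    structure(
      list(ec50 = NA_real_, hill = NA_real_, defined = FALSE,
           reason = reason, n_used = n_used),
      class = "median_effect_fit"
    )
  }
  ok <- is.finite(d) & is.finite(effect) & d > 0 & effect > 0 & effect < 1
  if (sum(ok) < 2L) return(undef("too few usable points", sum(ok)))
  x <- log10(d[ok])
  y <- log10(1 / effect[ok] - 1)
  if (length(unique(x)) < 2L) return(undef("too few distinct doses", sum(ok)))
  co <- stats::coef(stats::lm(y ~ x))
  h <- unname(co[2])
  if (!is.finite(h) || h < 0) return(undef("fitted Hill slope < 0", sum(ok)))
  # intercept = -h * log10(C)
  ec50 <- 10^(-unname(co[1]) / h)
  structure(
    list(ec50 = ec50, hill = h, defined = TRUE, reason = NULL,
         n_used = sum(ok)),
    class = "median_effect_fit"
  )
}

# Median-effect inverse dose at effect E (fraction unaffected in (0,1)):
# D(E) = C * (1/E - 1)^(1/h). NA outside (0,1).
.median_effect_inverse <- function(E, ec50, hill) {
  out <- rep(NA_real_, length(E))
  ok <- is.finite(E) & E > 0 & E < 1
  out[ok] <- ec50 * (1 / E[ok] - 1)^(1 / hill)
  out
}
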
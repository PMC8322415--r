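#' Two-drug MuSyC surface parameters
#'
#' The full parameter set of the four-state mass-action model underlying the
#' two-dimensional Hill dose-response surface. The four states are the
#' unaffected population U and the populations affected by drug 1 alone (A1),
#' drug 2 alone (A2), or both (A12); their characteristic effects are
#' `e0, e1, e2, e3`. Each drug has a monotherapy EC50 (`c1`, `c2`) and Hill
#' slope (`h1`, `h2`). Synergy enters through:
#'
#' * `alpha12`, `alpha21` — potency synergy: the fold change in drug 2's
#'   (resp. drug 1's) potency induced by the other drug. `alpha = 0` is the
#'   mutually exclusive limit in which the doubly affected state is
#'   unreachable.
#' * `gamma12`, `gamma21` — cooperativity synergy: the fold change in one
#'   drug's Hill slope induced by the other.
#'
#' The efficacy-synergy parameter beta is derived from the effects, see
#' [compute_beta()]. Forward rate constants are fixed at `r1 = r2 = 100` by
#' convention (the steady state depends on rate ratios only); reverse rates
#' follow from the mass-action definition of the EC50,
#' `r_rev_j = r_j * C_j^(h_j)`.
#'
#' @param e0,e1,e2,e3 Effects of states U, A1, A2, A12 (assay units).
#' @param c1,c2 Monotherapy EC50s (> 0).
#' @param h1,h2 Monotherapy Hill slopes (> 0).
#' @param alpha12,alpha21 Potency-synergy fold changes (>= 0; 0 allowed for
#'   the mutually exclusive / sham regime even though fitting bounds
#'   log10(alpha) to \[-4, 4\]).
#' @param gamma12,gamma21 Cooperativity-synergy fold changes (> 0).
#' @param r1,r2 Forward rate constants (> 0, default 100).
#' @return An object of class `musyc_params`.
#' @examples
#' p <- musyc_params(e0 = 1, e1 = 0.3, e2 = 0.5, e3 = 0.1,
#'                   c1 = 1, c2 = 1, h1 = 1, h2 = 1,
#'                   alpha12 = 3, alpha21 = 0.5)
#' evaluate_surface(1, 1, p)
#' compute_beta(p)
#' @export
musyc_params <- function(e0, e1, e2, e3, c1, c2, h1, h2,
                         alpha12 = 1, alpha21 = 1,
                         gamma12 = 1, gamma21 = 1,
                         r1 = 100, r2 = 100) {
  for (nm in c("e0", "e1", "e2", "e3")) {
    .stopifnot_scalar_number(get(nm), nm)
  }
  .stopifnot_scalar_number(c1, "c1", positive = TRUE)
  .stopifnot_scalar_number(c2, "c2", positive = TRUE)
  .stopifnot_scalar_number(h1, "h1", positive = TRUE)
  .stopifnot_scalar_number(h2, "h2", positive = TRUE)
  .stopifnot_scalar_number(alpha12, "alpha12", nonnegative = TRUE)
  .stopifnot_scalar_number(alpha21, "alpha21", nonnegative = TRUE)
  .stopifnot_scalar_number(gamma12, "gamma12", positive = TRUE)
  .stopifnot_scalar_number(gamma21, "gamma21", positive = TRUE)
  .stopifnot_scalar_number(r1, "r1", positive = TRUE)
  .stopifnot_scalar_number(r2, "r2", positive = TRUE)
  structure(
    list(e0 = e0, e1 = e1, e2 = e2, e3 = e3, c1 = c1, c2 = c2,
         h1 = h1, h2 = h2, alpha12 = alpha12, alpha21 = alpha21,
         gamma12 = gamma12, gamma21 = gamma21, r1 = r1, r2 = r2),
    class = "musyc_params"
  )
}

#' @export
print.musyc_params <- function(x, ...) {
  cat("MuSyC surface parameters\n")
  cat(sprintf("  effects:  E0 = %g, E1 = %g, E2 = %g, E3 = %g\n",
              x$e0, x$e1, x$e2, x$e3))
  cat(sprintf("  potency:  C1 = %g, C2 = %g; slopes h1 = %g, h2 = %g\n",
              x$c1, x$c2, x$h1, x$h2))
  cat(sprintf("  synergy:  alpha12 = %g, alpha21 = %g, gamma12 = %g, gamma21 = %g\n",
              x$alpha12, x$alpha21, x$gamma12, x$gamma21))
  invisible(x)
}

# Monotherapy Hill parameters of one drug embedded in a surface.
.mono_hill <- function(p, drug) {
  if (drug == 1L) {
    hill_params(p$e0, p$e1, p$c1, p$h1)
  } else {
    hill_params(p$e0, p$e2, p$c2, p$h2)
  }
}

# The eight dose-dependent rate terms of the four-state model at (d1, d2).
# t1, t2: drugging of U; g12, g21: drugging of A1 -> A12 and A2 -> A12
# (scaled by alpha and gamma); rm1, rm2 and their gamma powers: reverse rates.
.rate_terms <- function(d1, d2, p) {
  list(
    t1 = p$r1 * .pow_clipped(d1, p$h1),
    t2 = p$r2 * .pow_clipped(d2, p$h2),
    rm1 = p$r1 * .pow_clipped(p$c1, p$h1),
    rm2 = p$r2 * .pow_clipped(p$c2, p$h2),
    g12 = .pow_clipped(p$r2, p$gamma12) *
      .pow_clipped(p$alpha12 * d2, p$gamma12 * p$h2),
    g21 = .pow_clipped(p$r1, p$gamma21) *
      .pow_clipped(p$alpha21 * d1, p$gamma21 * p$h1)
  )
}

#' Steady-state transition matrix of the four-state model
#'
#' Builds the 4x4 matrix M whose rows are the steady-state balance equations
#' for U, A1 and A2 (the fourth balance equation is linearly dependent: the
#' dynamic system only has rank 3) plus the conservation row of ones, so
#' that the state vector solves `M [U A1 A2 A12]' = [0 0 0 1]'`.
#'
#' @param d1,d2 Doses (scalars, >= 0, finite).
#' @param p A [musyc_params()] object.
#' @return A 4x4 numeric matrix with dimnames U, A1, A2, A12.
#' @export
build_transition_matrix <- function(d1, d2, p) {
  stopifnot(inherits(p, "musyc_params"))
  .stopifnot_scalar_number(d1, "d1", nonnegative = TRUE)
  .stopifnot_scalar_number(d2, "d2", nonnegative = TRUE)
  r <- .rate_terms(d1, d2, p)
  rm2g <- .pow_clipped(r$rm2, p$gamma12)
  rm1g <- .pow_clipped(r$rm1, p$gamma21)
  m <- rbind(
    c(-(r$t1 + r$t2), r$rm1,            r$rm2,            0),
    c(r$t1,           -(r$rm1 + r$g12), 0,                rm2g),
    c(r$t2,           0,                -(r$g21 + r$rm2), rm1g),
    c(1,              1,                1,                1)
  )
  dimnames(m) <- list(
    c("dU", "dA1", "dA2", "conservation"),
    c("U", "A1", "A2", "A12")
  )
  m
}

#' Steady-state population fractions
#'
#' Solves the linear system `M s = (0, 0, 0, 1)` for the state fractions at
#' one dose pair, using a row-equilibrated direct solve (never an explicit
#' matrix inverse). Rows are rescaled by their largest magnitude first —
#' harmless because the first three rows are homogeneous — which keeps the
#' solve stable when dose/EC50 power terms span many orders of magnitude. If
#' the solve fails or its residual exceeds 1e-8 the function falls back to a
#' least-squares solve of all four (rank-3) balance equations plus the
#' conservation row.
#'
#' @inheritParams build_transition_matrix
#' @return A named numeric vector (U, A1, A2, A12) in \[0, 1\] summing to 1.
#' @export
solve_state_populations <- function(d1, d2, p) {
  m <- build_transition_matrix(d1, d2, p)
  b <- c(0, 0, 0, 1)
  scale <- apply(abs(m), 1, max)
  scale[scale == 0 | !is.finite(scale)] <- 1
  ms <- m / scale
  bs <- b / scale
  s <- tryCatch(solve(ms, bs), error = function(e) NULL)
  resid_ok <- !is.null(s) && all(is.finite(s)) &&
    max(abs(ms %*% s - bs)) <= 1e-8
  if (!resid_ok) {
    # full rank-3 system: all four balance rows plus conservation
    r <- .rate_terms(d1, d2, p)
    rm2g <- .pow_clipped(r$rm2, p$gamma12)
    rm1g <- .pow_clipped(r$rm1, p$gamma21)
    row4 <- c(0, r$g12, r$g21, -(rm1g + rm2g))
    a <- rbind(m[1:3, , drop = FALSE], row4, c(1, 1, 1, 1))
    sc <- apply(abs(a), 1, max)
    sc[sc == 0 | !is.finite(sc)] <- 1
    rhs <- c(0, 0, 0, 0, 1) / sc
    s <- tryCatch(qr.solve(a / sc, rhs), error = function(e) NULL)
    if (is.null(s) || any(!is.finite(s))) {
      stop("degenerate surface: steady-state system is numerically singular",
           call. = FALSE)
    }
  }
  s <- pmin(pmax(as.numeric(s), 0), 1)
  s <- s / sum(s)
  names(s) <- c("U", "A1", "A2", "A12")
  s
}

# Vectorized steady-state fractions via cofactor (Cramer) expansion along
# the conservation row: s_i = cof_i / sum(cof). Row-rescaling the three
# balance rows multiplies every cofactor by the same constant, so ratios are
# exact; this keeps products of large rate terms inside double range.
# Returns a list of vectors U, A1, A2, A12.
.states_vec <- function(d1, d2, p) {
  r <- .rate_terms(d1, d2, p)
  rm2g <- .pow_clipped(r$rm2, p$gamma12)
  rm1g <- .pow_clipped(r$rm1, p$gamma21)
  n <- max(length(d1), length(d2))
  one <- rep(1, n)
  # balance rows (a, b, c) x columns (U, A1, A2, A12)
  a1 <- -(r$t1 + r$t2); a2 <- r$rm1 * one; a3 <- r$rm2 * one; a4 <- 0 * one
  b1 <- r$t1 + 0 * one; b2 <- -(r$rm1 + r$g12); b3 <- 0 * one; b4 <- rm2g * one
  c1 <- r$t2 + 0 * one; c2 <- 0 * one; c3 <- -(r$g21 + r$rm2); c4 <- rm1g * one
  sc_a <- pmax(abs(a1), abs(a2), abs(a3), abs(a4)); sc_a[sc_a == 0] <- 1
  sc_b <- pmax(abs(b1), abs(b2), abs(b3), abs(b4)); sc_b[sc_b == 0] <- 1
  sc_c <- pmax(abs(c1), abs(c2), abs(c3), abs(c4)); sc_c[sc_c == 0] <- 1
  a1 <- a1 / sc_a; a2 <- a2 / sc_a; a3 <- a3 / sc_a; a4 <- a4 / sc_a
  b1 <- b1 / sc_b; b2 <- b2 / sc_b; b3 <- b3 / sc_b; b4 <- b4 / sc_b
  c1 <- c1 / sc_c; c2 <- c2 / sc_c; c3 <- c3 / sc_c; c4 <- c4 / sc_c
  det3 <- function(p1, p2, p3, q1, q2, q3, r1, r2, r3) {
    p1 * (q2 * r3 - q3 * r2) - p2 * (q1 * r3 - q3 * r1) +
      p3 * (q1 * r2 - q2 * r1)
  }
  cof <- list(
    -det3(a2, a3, a4, b2, b3, b4, c2, c3, c4),
    det3(a1, a3, a4, b1, b3, b4, c1, c3, c4),
    -det3(a1, a2, a4, b1, b2, b4, c1, c2, c4),
    det3(a1, a2, a3, b1, b2, b3, c1, c2, c3)
  )
  tot <- cof[[1]] + cof[[2]] + cof[[3]] + cof[[4]]
  list(U = cof[[1]] / tot, A1 = cof[[2]] / tot,
       A2 = cof[[3]] / tot, A12 = cof[[4]] / tot)
}

#' Evaluate the two-dimensional Hill dose-response surface
#'
#' The measured effect at a dose pair is the population-weighted average of
#' the four state effects, `E = E0 U + E1 A1 + E2 A2 + E3 A12`, with the
#' state fractions at the mass-action steady state. The surface reduces to
#' each drug's monotherapy Hill curve on the dose axes, and at saturating
#' doses of one drug reduces to a one-dimensional Hill curve in the other
#' with plateau `E3`, EC50 `C/alpha` and slope `gamma * h`.
#'
#' `d1` and `d2` are recycled to a common length; the computation is
#' vectorized (a cofactor solve of the same steady-state system as
#' [solve_state_populations()]).
#'
#' @param d1,d2 Dose vectors (>= 0, finite), recycled.
#' @param p A [musyc_params()] object.
#' @return Effect values.
#' @export
evaluate_surface <- function(d1, d2, p) {
  stopifnot(inherits(p, "musyc_params"))
  .check_doses(d1, "d1")
  .check_doses(d2, "d2")
  n <- max(length(d1), length(d2))
  d1 <- rep_len(d1, n)
  d2 <- rep_len(d2, n)
  s <- .states_vec(d1, d2, p)
  p$e0 * s$U + p$e1 * s$A1 + p$e2 * s$A2 + p$e3 * s$A12
}

#' Efficacy synergy beta
#'
#' Beta measures the fractional gain in maximal effect of the combination
#' over the strongest single agent, relative to the total effect window of
#' that agent: `beta = (min(E1, E2) - E3) / (E0 - min(E1, E2))` for
#' decreasing (viability-like) readouts. `beta > 0` means the combination's
#' plateau beats the best monotherapy plateau. For increasing readouts the
#' strongest agent is the `max` and the ratio is flipped accordingly.
#'
#' @param p A [musyc_params()] object.
#' @param orientation `"decreasing"` (effect falls with dose, default) or
#'   `"increasing"`.
#' @return Beta, dimensionless; `NA` when the denominator vanishes
#'   (strongest single agent has no effect window).
#' @export
compute_beta <- function(p, orientation = c("decreasing", "increasing")) {
  stopifnot(inherits(p, "musyc_params"))
  orientation <- match.arg(orientation)
  .beta_from_effects(p$e0, p$e1, p$e2, p$e3, orientation)
}

.beta_from_effects <- function(e0, e1, e2, e3, orientation = "decreasing") {
  if (orientation == "decreasing") {
    strongest <- pmin(e1, e2)
    num <- strongest - e3
    den <- e0 - strongest
  } else {
    strongest <- pmax(e1, e2)
    num <- e3 - strongest
    den <- strongest - e0
  }
  ifelse(den == 0, NA_real_, num / den)
}

#' Sham surfaces: the model's and the analytically true one
#'
#' In a sham experiment a single drug is split notionally into "drug 1" and
#' "drug 2". Under the sham constraints (mutually exclusive action
#' `alpha12 = alpha21 = 0`, shared `C`, `h` and plateau `E1`), the
#' mass-action surface reduces to
#' `(E0 + E1 (d1^h + d2^h)/C^h) / (1 + (d1^h + d2^h)/C^h)`
#' (`sham_surface_musyc`), whereas the truly correct sham response is the
#' monotherapy curve evaluated at the summed dose, `H(d1 + d2)`
#' (`sham_surface_true`). The two agree everywhere if and only if `h = 1`:
#' for `h != 1` the binomial expansion of `(d1 + d2)^h` carries cross-terms
#' (mixed partially-drugged states) absent from the mutually exclusive
#' model. That discrepancy is the Hill-slope bias that sham-compliant
#' (Loewe-type) synergy frameworks impose on real combinations.
#'
#' @param d1,d2 Dose vectors (>= 0), recycled.
#' @param ec50,hill Shared EC50 and Hill slope of the sham drug.
#' @param e0,e1 Baseline and plateau effects.
#' @return Effect values.
#' @export
sham_surface_musyc <- function(d1, d2, ec50, hill, e0, e1) {
  .check_doses(d1, "d1")
  .check_doses(d2, "d2")
  .stopifnot_scalar_number(ec50, "ec50", positive = TRUE)
  .stopifnot_scalar_number(hill, "hill", positive = TRUE)
  u <- (.pow_clipped(d1, hill) + .pow_clipped(d2, hill)) /
    .pow_clipped(ec50, hill)
  (e0 + e1 * u) / (1 + u)
}

#' @rdname sham_surface_musyc
#' @export
sham_surface_true <- function(d1, d2, ec50, hill, e0, e1) {
  .check_doses(d1, "d1")
  .check_doses(d2, "d2")
  hill_1d(d1 + d2, hill_params(e0, e1, ec50, hill))
}

#' Affected/unaffected ratio for multiple mutually exclusive drugs
#'
#' For n mutually exclusive inhibitors with Hill kinetics, the mass-action
#' steady state gives the affected-to-unaffected ratio as the sum of
#' per-drug median-effect terms, `sum_j (d_j/C_j)^(h_j)`
#' (`ci_affected_ratio_correct`). The classical combination-index
#' derivation instead factors a common exponent outside the sum,
#' `(sum_j d_j/C_j)^h` (`ci_affected_ratio_invalid`) — an algebra error
#' whose two forms agree only when every Hill slope equals 1. The
#' discrepancy is the source of the combination index's Hill-slope bias.
#'
#' @param doses,ec50s Positive numeric vectors of equal length.
#' @param hill Single shared Hill slope (invalid form).
#' @param hills Per-drug Hill slopes (correct form).
#' @return The dimensionless ratio A/U.
#' @export
ci_affected_ratio_invalid <- function(doses, ec50s, hill) {
  stopifnot(length(doses) == length(ec50s), all(doses > 0), all(ec50s > 0))
  .stopifnot_scalar_number(hill, "hill", positive = TRUE)
  sum(doses / ec50s)^hill
}

#' @rdname ci_affected_ratio_invalid
#' @export
ci_affected_ratio_correct <- function(doses, ec50s, hills) {
  stopifnot(length(doses) == length(ec50s), all(doses > 0), all(ec50s > 0))
  hills <- rep_len(hills, length(doses))
  stopifnot(all(hills > 0))
  sum((doses / ec50s)^hills)
}

#' Number of synergy parameters for an N-drug combination
#'
#' The mass-action surface model generalizes to N drugs on a hyper-cube of
#' 2^N states; the number of synergy parameters beyond the single-drug Hill
#' parameters (counting cooperativity synergies) scales as
#' `2^N (N + 1) - 3N - 1`. For two drugs this is 5: alpha12, alpha21, beta,
#' gamma12, gamma21.
#'
#' @param n Integer number of drugs, >= 2.
#' @return Integer parameter count.
#' @export
synergy_param_count <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) ||
      n != round(n) || n < 2) {
    stop("`n` must be an integer >= 2", call. = FALSE)
  }
  as.integer(2^n * (n + 1) - 3 * n - 1)
}
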
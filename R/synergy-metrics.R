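#' Excess-over-Bliss synergy score
#'
#' Bliss independence expects the unaffected fractions under the two drugs
#' to multiply: `E_expected(a, b) = H1(a) * H2(b)` for percent-scale,
#' decreasing readouts. The score is the excess of that expectation over the
#' combination effect, `H1(a) H2(b) - E(a, b)`: positive values are
#' synergistic. By default the combination effect is evaluated on the fitted
#' surface rather than a raw measurement, since dose anchors such as the
#' EC50 pair are rarely measured exactly; pass `effect` to score a raw
#' observation instead.
#'
#' @param p A [musyc_params()] object (the fitted surface; its embedded
#'   monotherapy parameters define `H1`, `H2`).
#' @param dose_pair Length-2 dose pair `(d1, d2)` at which to score. Common
#'   anchors: the EC50 pair `(C1, C2)` or the maximum tested doses.
#' @param effect Optional measured combination effect at `dose_pair`;
#'   default evaluates the surface.
#' @return The excess score (assay units).
#' @export
bliss_score <- function(p, dose_pair, effect = NULL) {
  stopifnot(inherits(p, "musyc_params"), length(dose_pair) == 2L)
  h1 <- hill_1d(dose_pair[1], .mono_hill(p, 1L))
  h2 <- hill_1d(dose_pair[2], .mono_hill(p, 2L))
  E <- if (is.null(effect)) {
    evaluate_surface(dose_pair[1], dose_pair[2], p)
  } else {
    effect
  }
  h1 * h2 - E
}

#' Loewe additivity index
#'
#' The dose-equivalence sum `d1 / H1inv(E) + d2 / H2inv(E)`, where `Hinv` is
#' the monotherapy inverse Hill curve and `E` the combination effect at the
#' dose pair. An index of 1 is additive under the Dose Equivalence
#' Principle, below 1 synergistic, above 1 antagonistic (see
#' [neg_log10_score()] for the signed transform). The index is undefined
#' (`NA`) when the combination effect lies beyond either single drug's
#' plateau, where the inverse curves do not exist.
#'
#' @inheritParams bliss_score
#' @return The index (> 0) or `NA` when undefined.
#' @export
loewe_index <- function(p, dose_pair, effect = NULL) {
  stopifnot(inherits(p, "musyc_params"), length(dose_pair) == 2L)
  E <- if (is.null(effect)) {
    evaluate_surface(dose_pair[1], dose_pair[2], p)
  } else {
    effect
  }
  inv1 <- hill_1d_inverse(E, .mono_hill(p, 1L))
  inv2 <- hill_1d_inverse(E, .mono_hill(p, 2L))
  if (is.na(inv1) || is.na(inv2)) return(NA_real_)
  dose_pair[1] / inv1 + dose_pair[2] / inv2
}

#' Highest-single-agent synergy score
#'
#' Excess of the combination effect over the better of the two monotherapy
#' effects at the same doses: `min(H1(a), H2(b)) - E(a, b)` for decreasing
#' readouts (the stronger agent achieves the lower effect), with min/max
#' flipped for increasing readouts. Positive values are synergistic.
#'
#' @inheritParams bliss_score
#' @param orientation `"decreasing"` or `"increasing"`.
#' @return The excess score (assay units).
#' @export
hsa_score <- function(p, dose_pair, effect = NULL,
                      orientation = c("decreasing", "increasing")) {
  stopifnot(inherits(p, "musyc_params"), length(dose_pair) == 2L)
  orientation <- match.arg(orientation)
  h1 <- hill_1d(dose_pair[1], .mono_hill(p, 1L))
  h2 <- hill_1d(dose_pair[2], .mono_hill(p, 2L))
  E <- if (is.null(effect)) {
    evaluate_surface(dose_pair[1], dose_pair[2], p)
  } else {
    effect
  }
  if (orientation == "decreasing") min(h1, h2) - E else E - max(h1, h2)
}

#' Chou-Talalay combination index
#'
#' Follows the CompuSyn procedure: the two-parameter median-effect equation
#' is fit to each drug's monotherapy rows ([median_effect_fit()], which
#' assumes the effect runs from 1 to 0 and drops points outside (0, 1)),
#' then `CI = d1 / D1(E) + d2 / D2(E)` where `Dj(E) = Cj (1/E - 1)^(1/hj)`
#' is the median-effect inverse and `E` the combination effect at the dose
#' pair (the observed value if a matching row exists, otherwise supplied via
#' `effect`). CI below 1 is called synergistic.
#'
#' The result is flagged undefined (`NA` with a `reason` attribute) when
#' either median-effect fit fails (too few usable points, negative slope) or
#' the combination effect is outside (0, 1).
#'
#' @param data Dose-response data frame with monotherapy rows for both
#'   drugs.
#' @param dose_pair Length-2 combination dose pair.
#' @param effect Combination effect at `dose_pair`; defaults to the mean of
#'   matching rows in `data`.
#' @return The index, or `NA` with attribute `reason`.
#' @export
combination_index <- function(data, dose_pair, effect = NULL) {
  data <- .as_dose_response(data)
  stopifnot(length(dose_pair) == 2L)
  undef <- function(reason) structure(NA_real_, reason = reason)
  mono1 <- data[data$d2 == 0, ]
  mono2 <- data[data$d1 == 0, ]
  f1 <- median_effect_fit(mono1$d1, mono1$effect)
  f2 <- median_effect_fit(mono2$d2, mono2$effect)
  if (!f1$defined) return(undef(paste0("drug 1: ", f1$reason)))
  if (!f2$defined) return(undef(paste0("drug 2: ", f2$reason)))
  if (is.null(effect)) {
    hit <- data$d1 == dose_pair[1] & data$d2 == dose_pair[2]
    if (!any(hit)) {
      return(undef("no measured effect at dose pair; supply `effect`"))
    }
    effect <- mean(data$effect[hit])
  }
  if (!is.finite(effect) || effect <= 0 || effect >= 1) {
    return(undef("combination effect outside (0, 1)"))
  }
  D1 <- .median_effect_inverse(effect, f1$ec50, f1$hill)
  D2 <- .median_effect_inverse(effect, f2$ec50, f2$hill)
  dose_pair[1] / D1 + dose_pair[2] / D2
}

#' Expected Bliss gain over the stronger single agent
#'
#' At saturating doses the Bliss expectation for the combination is
#' `E1 * E2`, so the expected improvement over the stronger single agent is
#' `delta = min(E1, E2) - E1 E2` (decreasing percent scale). Delta depends
#' on the single-agent plateaus alone: it peaks at 0.25 for two
#' half-efficacious drugs (`E1 = E2 = 0.5`) and shrinks toward the corners
#' of the unit square — the efficacy-range bias by which Bliss demands the
#' most from combinations of moderately efficacious drugs.
#'
#' @param e1,e2 Single-agent plateau effects in \[0, 1\].
#' @return Delta, dimensionless.
#' @export
bliss_delta <- function(e1, e2) {
  stopifnot(is.numeric(e1), is.numeric(e2))
  if (any(!is.finite(c(e1, e2))) || any(c(e1, e2) < 0) ||
      any(c(e1, e2) > 1)) {
    stop("`e1` and `e2` must lie in [0, 1]", call. = FALSE)
  }
  pmin(e1, e2) - e1 * e2
}

#' Hill-slope bias of the Loewe index
#'
#' Quantifies how much of an observed Loewe score is explained purely by
#' the drugs' Hill slopes. The combination effect is predicted on the
#' counterfactual mutually exclusive surface (`alpha12 = alpha21 = 0`) that
#' retains all single-drug parameters, and the Loewe index of that
#' zero-potency-synergy surface is returned on the `-log10` scale. For
#' `h1 = h2 = 1` the counterfactual satisfies dose equivalence exactly and
#' the bias is 0; slopes below 1 push the bias positive (spurious synergy),
#' slopes above 1 negative (spurious antagonism). Subtracting this bias
#' from an observed `-log10` Loewe score isolates the potency/efficacy
#' contribution.
#'
#' @param p A [musyc_params()] object (the fitted surface).
#' @param dose_pair Length-2 dose pair, typically `(C1, C2)`.
#' @return The bias on the `-log10` scale, or `NA` where the counterfactual
#'   Loewe index is undefined.
#' @export
loewe_hill_bias <- function(p, dose_pair) {
  stopifnot(inherits(p, "musyc_params"))
  p0 <- p
  p0$alpha12 <- 0
  p0$alpha21 <- 0
  idx <- loewe_index(p0, dose_pair)
  if (is.na(idx) || idx <= 0) return(NA_real_)
  -log10(idx)
}

#' Signed -log10 transform of a dose-ratio synergy index
#'
#' Puts Loewe and combination-index values on a signed scale matching the
#' excess-style scores: `-log10(index)` is positive for synergy (index < 1)
#' and negative for antagonism. Values are clipped at +/- 10 for tabular
#' output; non-positive or undefined indices give `NA`.
#'
#' @param index Numeric vector of indices.
#' @return Signed scores.
#' @export
neg_log10_score <- function(index) {
  out <- rep(NA_real_, length(index))
  ok <- is.finite(index) & index > 0
  out[ok] <- pmin(pmax(-log10(index[ok]), -10), 10)
  out
}
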
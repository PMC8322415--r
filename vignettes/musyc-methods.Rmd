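---
title: "Mass-action dose-response surfaces and decoupled drug synergy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mass-action dose-response surfaces and decoupled drug synergy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musycr)
```

## The model

A single drug acting by mass action shuttles a population between an
unaffected state U and an affected state A, with forward rate
$r \, d^{h}$ and reverse rate $r_{-}$. At steady state
$A/U = (d/C)^{h}$ with $C \equiv (r_{-}/r)^{1/h}$ — the median-effect
relation — and if the two states express effects $E_0$ and $E_1$, the
measured response is the familiar four-parameter Hill curve

$$E(d) = E_1 + \frac{E_0 - E_1}{1 + (d/C)^{h}}.$$

For two concurrent drugs the state space is the square
$\{U, A_1, A_2, A_{1,2}\}$. The transitions out of the singly affected
states carry the synergy parameters: drug 2 drives $A_1 \to A_{1,2}$ with
rate $r_2^{\gamma_{12}} (\alpha_{12} d_2)^{\gamma_{12} h_2}$, so
$\alpha_{12}$ is the fold change in drug 2's potency induced by drug 1 and
$\gamma_{12}$ the fold change in its Hill slope (and symmetrically for
$\alpha_{21}, \gamma_{21}$). Setting the first three balance equations to
zero and appending the conservation row $U + A_1 + A_2 + A_{1,2} = 1$
gives a rank-4 linear system $M s = (0,0,0,1)^T$; the response surface is

$$E(d_1, d_2) = (E_0, E_1, E_2, E_3) \cdot s(d_1, d_2).$$

Efficacy synergy is the derived quantity
$\beta = \big(\min(E_1, E_2) - E_3\big) / \big(E_0 - \min(E_1, E_2)\big)$:
the fractional improvement of the combined plateau over the best single
agent. The surface reduces to each monotherapy curve on the axes, and at
saturating co-drug to a one-dimensional Hill curve with plateau $E_3$,
EC50 $C/\alpha$ and slope $\gamma h$ — which is why $\alpha = 10$ reads
directly as "a ten-fold potency gain".

Two classical null models are special cases. With $E_0 = 1$,
$\alpha = \gamma = 1$ and $E_3 = E_1 E_2$ the surface is exactly the
product of the monotherapy curves (multiplicative survival, the Bliss
null). With $\alpha_{12} = \alpha_{21} = 0$ (mutually exclusive action)
and $h_1 = h_2 = 1$ every isobole is linear and the dose-equivalence sum
is identically one (the Loewe null). The model therefore spans both
principles, which no single classical metric does.

```{r nulls}
# Bliss null: product surface
p_msp <- musyc_params(1, 0.5, 0.5, 0.25, 1, 1, 1, 1)
evaluate_surface(1, 1, p_msp)        # 0.75 * 0.75
# Loewe null: dose-equivalence sum is 1
p_dep <- musyc_params(1, 0, 0, 0, 1, 1, 1, 1, alpha12 = 0, alpha21 = 0)
loewe_index(p_dep, c(0.3, 2.5))
```

## Numerical evaluation

`solve_state_populations()` performs a row-equilibrated direct solve of
$M s = e_4$ (no explicit inverse), falling back to a least-squares solve
of all four (rank-3) balance rows plus the conservation row when the
residual exceeds 1e-8. The vectorized path used by `evaluate_surface()`
expands the same system by cofactors along the conservation row, after
rescaling each balance row by its largest entry — row scaling multiplies
every cofactor by the same constant, so the state fractions are unchanged
while products of rate terms stay inside double range. Dose/EC50 power
terms are computed in log space and clipped at $e^{\pm 700}$. The two
paths agree to 1e-10 in the tests, and both agree with long-time
integration of the mass-action ODE system (an independent oracle run with
`deSolve`) to 1e-5 over random parameter sets with $h \in [0.5, 3]$,
$\log_{10}\alpha \in [-2, 2]$, $\gamma \in [0.5, 2]$.

$\alpha = 0$ is accepted by the evaluator even though fitting bounds
$\log_{10}\alpha$ to $[-4, 4]$: the mutually exclusive and sham regimes
need it exactly, so the evaluation and fitting domains deliberately
differ.

## Fitting

`fit_musyc()` is a three-stage pipeline.

1. Each drug's monotherapy rows are fit with the four-parameter Hill
   equation by bounded nonlinear least squares (`minpack.lm::nls.lm`,
   Levenberg–Marquardt with box constraints). EC50 and slope are
   parameterized as $\log_{10}$ values: the log-linearized Hill equation
   has intercept $-h \log C$, so $h$ and $C$ are strongly collinear and
   the optimizer behaves far better in log coordinates. Initial guesses
   are deterministic (median effects at the dose extremes, geometric-mean
   dose, $h = 1$). A fit whose baseline and plateau differ by less than 1%
   of the observed effect range is rejected as flat.
2. The full surface is fit the same way, initialized at the stage-1
   estimates with $E_3 = \min(E_1, E_2)$ and $\alpha = \gamma = 1$.
   Parameters shared with stage 1 are bounded to their stage-1 estimate
   $\pm 3$ standard errors (the multiplier is configurable), intersected
   with the assay's effect bounds; $\log_{10}\alpha \in [-4, 4]$. The
   residual Jacobian is computed by forward differences with an absolute
   step floor of 1e-7 — a purely relative step freezes any parameter whose
   current value is near zero, which $\log_{10}$-scale parameters
   routinely are. $\gamma_{12}, \gamma_{21}$ are fixed at 1 by default
   (they rarely improve fit quality and the model is nested); an opt-in
   flag fits them.
3. Uncertainty comes from a Monte-Carlo scheme: Gaussian noise
   $N(0, \sigma)$ with $\sigma$ equal to the root-mean-square residual of
   the best fit is added to the best-fit predictions at the observed
   doses, and the surface is refit from the best-fit parameters; 100 such
   refits (by default) form an ensemble, and each parameter's 95% interval
   takes the $k$-th smallest and $k$-th largest ensemble values with
   $k = \lceil 0.025\,n \rceil$. Failed refits are dropped (never
   retried); if more than half fail, a wide-CI flag is raised. Intervals
   are asymmetric by construction (slope uncertainty is log-normal-like)
   and are widened, when necessary, to contain the point estimate. A
   single integer seed drives the whole noise stream.

A combination passes QC when $R^2 > 0.7$ and both fitted EC50s lie below
the maximum tested dose of their drug. Effect bounds are left to
configuration because they are assay facts: for normalized-viability
screens a near-pinned baseline (`e0_bounds = c(0.99, 1.01)`, plateaus in
$[0, 2.5]$) is the sensible choice; the defaults are unbounded so
arbitrary effect scales work.

### What the intervals do and do not deliver

On a noiseless checkerboard the pipeline recovers generating parameters
to better than 1e-3 relative error, and interval widths collapse with the
residual. Under noise, the Monte-Carlo percentile intervals are a
curvature-at-the-optimum approximation: in our simulations (8x8 grid, 2%
additive noise) their per-parameter coverage of the generating values is
roughly 85–95%, not a uniform 95% — the true sampling spread along the
collinear EC50/slope/potency-synergy directions is up to ~1.5x the
ensemble spread, $\sigma = \mathrm{RMS}$ slightly underestimates the
noise, and percentile intervals carry first-order coverage error for
skewed estimators. The intervals are honest uncertainty summaries for
ranking and screening, but should not be treated as exact 95% frequentist
intervals in the tails.

## The simulator

`generate_surface_data()` evaluates a known surface over a sampling
design and applies a noise model; it is the fixture generator for every
test and the engine for the bias sweeps. The default experiment in the
tests is an 8-dose checkerboard per drug (a zero anchor plus 7 log-spaced
doses spanning two decades either side of the EC50s, 64 wells) — the
shape of a typical combination-screen block — with additive Gaussian
noise at $\sigma = 0.02$ on a 0–1 effect scale, i.e. 2% of the full
window, a realistic noise floor for plate-based viability assays.
Proportional noise multiplies by $1 + N(0, \sigma)$. Effects are
deliberately not clipped to a nominal range: real assays report values
outside it, and range filtering is an analysis decision. The
`corners_edges` design implements the economical recommendation to pin
efficacy synergy at the four corners of the dose square and
potency/cooperativity at EC50-anchored edge points; it keeps a log-spaced
monotherapy series along each axis so the single-drug curves stay
identifiable. What the simulator does not emulate: plate and batch
effects, dose-dependent error structure, pipetting correlation between
neighboring wells, and temporally staggered dosing — so passing recovery
tests here demonstrates correctness of the estimator, not robustness to
every failure mode of real screens.

`generate_sham_data()` produces the classical self-combination thought
experiment: one drug under two labels, with the exact response
$H(d_1 + d_2)$. The mass-action model reproduces a sham only at $h = 1$;
for $h \ne 1$ the binomial cross-terms of $(d_1 + d_2)^h$ describe mixed
partially-bound states that are fully-affected in a sham but not in a
real combination. That is precisely why sham-compliant (dose-equivalence)
metrics carry a Hill-slope bias on real data, and why sham compliance is
a poor validity criterion.

## Classical metrics and their biases

`bliss_score()`, `loewe_index()` and `hsa_score()` follow the
excess-over-expectation and dose-ratio conventions on a decreasing
percent scale, evaluated by default on the fitted surface (EC50-anchored
dose pairs are rarely measured exactly; a raw-effect argument provides
the data-parity mode). Undefined Loewe values — combination effects
beyond a single-drug plateau — are explicit `NA`s, never dropped
silently. `combination_index()` reproduces the CompuSyn procedure,
including its exclusion rules (effects outside (0, 1), negative fitted
slopes) and therefore also its two systematic errors, which the package
exposes deliberately:

* the factored-exponent ratio $(\sum d_j / C_j)^h$ versus the correct
  $\sum (d_j/C_j)^{h_j}$ (`ci_affected_ratio_invalid()` /
  `ci_affected_ratio_correct()`), which coincide only at $h = 1$ and give
  $\mathrm{CI} = \sqrt{2}$ at the EC50 pair of an additive $h = 2$
  combination;
* the two-parameter median-effect fit, exact only for full-range curves
  and systematically biased for partial-efficacy drugs.

`loewe_hill_bias()` quantifies the first effect for Loewe itself: the
$-\log_{10}$ Loewe index of the mutually exclusive counterfactual surface
($\alpha = 0$, single-drug parameters retained), zero at $h = 1$,
positive (spurious synergy) for $h < 1$ and negative for $h > 1$.
Subtracting it from an observed score isolates the potency/efficacy
contribution. `bliss_delta()` captures the efficacy-range bias of
multiplicative-survival metrics: the expected gain
$\min(E_1, E_2) - E_1 E_2$ peaks at 0.25 for two half-efficacious drugs
and vanishes toward the corners of the unit square, so Bliss demands the
most from exactly the combinations of moderately efficacious agents.

`sweep_profiles()` scores grids of synergy profiles
$(\log\alpha_{12}, \log\alpha_{21}, \beta)$ with all four metrics at the
EC50 pair, reproducing the masking geometry: antagonistically potent but
synergistically efficacious profiles that HSA scores non-positive, the
region where strong potency synergy pushes the combination effect beyond
both plateaus and Loewe is undefined, and quadrants where Loewe calls
antagonistic-potency profiles synergistic. One caution from our own
sweeps: the sign of the Bliss excess for mixed-potency profiles
($\alpha_{12} > 1 > \alpha_{21}$, $\beta = 0$) is not constant across the
quadrant — it depends on which potency modulation dominates at the
anchor doses — so only the documented masking directions are asserted in
the tests.

## Numerical choices and degenerate inputs

* β→$E_3$ inversion in the simulator:
  $E_3 = \min(E_1, E_2) - \beta (E_0 - \min(E_1, E_2))$, with ties broken
  toward drug 1 (no observable consequence); a β implying $E_3 > E_0$ is
  a construction error.
* Median-effect regression excludes zero-dose rows (their log is
  undefined) in addition to the conventional effect-range exclusions.
* $-\log_{10}$ transforms are clipped at $\pm 10$ for tabular output.
* Degenerate steady-state systems raise an error rather than returning
  populations; constant-effect data fail the monotherapy fit with an
  explicit reason; zero-variance data make $R^2$ undefined and fail QC.
* Problem sizes in the test-suite simulations — 8x8 checkerboards, 100
  coverage replicates with 100 Monte-Carlo samples each, 50 random
  parameter sets for the ODE cross-check — were chosen as the smallest
  experiments that exercise each claim convincingly.

## Known limitations

Two-drug combinations only; monotonic sigmoidal monotherapies only
(multiphasic responses need a different response model); concurrent
dosing only. The fitter assumes homoscedastic noise when estimating
uncertainty. Monte-Carlo interval coverage is approximate, as quantified
above. The steady state of the four-state cycle is defined by the matrix
solve; for $\gamma \ne 1$ the cycle is not required to satisfy detailed
balance, and the ODE integration is used as a numerical oracle only.
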
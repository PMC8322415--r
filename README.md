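# musycr

Quantifying two-drug combination pharmacology with a mass-action
dose-response surface whose synergy parameters are decoupled by type.

## The problem

Combination screens need a number that says whether two drugs cooperate,
but the classical answers disagree with each other by construction. Bliss
independence assumes unaffected fractions multiply; Loewe additivity and
the Chou–Talalay combination index (CI) assume dose equivalence and
linear isoboles; highest single agent (HSA) just compares against the
better monotherapy. Each conflates distinct phenomena — a drug can make
its partner *more potent* without changing what the pair can *maximally
achieve*, and vice versa — and each carries structural biases: dose-
equivalence metrics inherit a Hill-slope bias from enforcing the sham
(self-combination) thought experiment, multiplicative-survival metrics
are hardest on combinations of moderately efficacious drugs, and CI adds
a derivation error that inflates antagonism whenever Hill slopes exceed
one.

The MuSyC framework (Multi-dimensional Synergy of Combinations) resolves
this by modeling the combination as a four-state mass-action system —
unaffected, affected by drug 1, by drug 2, by both — whose steady state
is a two-dimensional Hill surface:

```
E(d1, d2) = (E0, E1, E2, E3) · s(d1, d2),    M s = (0, 0, 0, 1)ᵀ
```

with per-drug EC50s `C` and Hill slopes `h`, and three decoupled synergy
types: potency synergy `α12, α21` (fold change of one drug's EC50 caused
by the other), efficacy synergy `β = (min(E1,E2) − E3)/(E0 − min(E1,E2))`
(gain of the combined plateau over the best single agent), and
cooperativity synergy `γ12, γ21` (fold change of Hill slope). Bliss's and
Loewe's null surfaces are exact special cases (`E3 = E1·E2` with `α=γ=1`,
and `α = 0` with `h = 1`, respectively), so the model spans both
principles and makes their biases computable.

The package provides, for users analyzing checkerboard (dose-matrix)
assays:

* the surface model and its steady-state solver (`musyc_params()`,
  `evaluate_surface()`, `solve_state_populations()`);
* a staged fitting pipeline — monotherapy Hill fits seeding a bounded
  nonlinear least-squares surface fit, with Monte-Carlo percentile 95%
  intervals and QC filters (`fit_musyc()`, `fit_config()`);
* classical metrics and their bias diagnostics (`bliss_score()`,
  `loewe_index()`, `hsa_score()`, `combination_index()`,
  `bliss_delta()`, `loewe_hill_bias()`);
* a checkerboard simulator for designs and noise models
  (`generate_surface_data()`, `generate_sham_data()`,
  `sweep_profiles()`);
* CSV/YAML input-output and a command-line interface
  (`read_dose_response_csv()`, `musyc_cli()`, `inst/cli/musyc`).

## Worked example

Simulate a noisy 8×8 checkerboard from a known surface — drug 1 triples
drug 2's potency (`α12 = 3`), drug 2 halves drug 1's (`α21 = 0.5`), and
the combined plateau (0.1) beats the best single agent (0.3) — then
refit it:

```r
library(musycr)

p_true <- musyc_params(e0 = 1, e1 = 0.3, e2 = 0.5, e3 = 0.1,
                       c1 = 1, c2 = 1, h1 = 1, h2 = 1,
                       alpha12 = 3, alpha21 = 0.5)
design <- sampling_design("grid",
                          doses1 = dose_grid(0.01, 100, 7),
                          doses2 = dose_grid(0.01, 100, 7))
dat <- generate_surface_data(p_true, design,
                             noise_model("additive_gaussian", 0.02, seed = 42))
fit <- fit_musyc(dat, fit_config(mc_samples = 100, seed = 42))
fit
```

```
MuSyC surface fit
  R-squared = 0.9942, RMS = 0.02134, QC pass
     parameter estimate    lower   upper
            E0   1.0076  0.99207  1.0233
            E1   0.3169  0.29535  0.3410
            E2   0.4917  0.46759  0.5043
            E3   0.1145  0.09413  0.1332
            C1   0.9309  0.81955  1.0731
            C2   0.9728  0.80147  1.2074
            h1   1.0431  0.95304  1.1393
            h2   0.9402  0.78972  1.0648
 log10_alpha12   0.6177  0.36090  0.8729
 log10_alpha21  -0.3006 -0.42186 -0.1753
          beta   0.2930  0.24311  0.3604
```

Every generating value sits inside its 95% interval: the fit reads the
combination as synergistically potent in the 1→2 direction
(`log10_alpha12 > 0`, i.e. α12 ≈ 4), antagonistically potent in the
2→1 direction, and synergistically efficacious (β ≈ 0.29 — the
combination achieves ~29% more of drug 1's effect window than drug 1
alone). Classical metrics at the fitted EC50 pair show how this profile
gets flattened into a single number:

```r
at <- c(fit$params$c1, fit$params$c2)
bliss_score(fit$params, at)      # 0.01496682  (mildly synergistic)
loewe_index(fit$params, at)      # NA — combination effect is beyond
                                 # drug 1's plateau, Loewe undefined
```

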
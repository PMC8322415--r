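#' Sampling designs for checkerboard simulations
#'
#' Describes where a simulated combination experiment measures the surface.
#'
#' * `grid`: the full factorial of `doses1 x doses2` (a classical
#'   checkerboard). Dose vectors must include 0 so the dataset carries the
#'   monotherapy anchors the fitting pipeline needs.
#' * `corners_edges`: the economical design recommended for constraining
#'   synergy parameters — the four corners `(0,0)`, `(d1max,0)`,
#'   `(0,d2max)`, `(d1max,d2max)` (pinning efficacy synergy) and the four
#'   edge anchors `(C1,0)`, `(C1,d2max)`, `(0,C2)`, `(d1max,C2)` (pinning
#'   potency/cooperativity synergy), supplemented by a log-spaced
#'   monotherapy dilution series along each axis so the single-drug curves
#'   remain identifiable.
#' * `custom`: an explicit data frame of `(d1, d2)` pairs.
#'
#' @param kind One of `"grid"`, `"corners_edges"`, `"custom"`.
#' @param doses1,doses2 For `grid`: per-drug dose vectors including 0.
#' @param d1max,d2max,c1,c2 For `corners_edges`: maximum tested doses and
#'   the EC50 anchors.
#' @param n_mono For `corners_edges`: points in each monotherapy dilution
#'   series (including zero dose), default 8.
#' @param pairs For `custom`: data frame with columns `d1`, `d2`.
#' @param replicates Replicates per dose pair, default 1.
#' @return A list of class `sampling_design` with a resolved `pairs` data
#'   frame.
#' @seealso [dose_grid()] for building log-spaced dose vectors.
#' @export
sampling_design <- function(kind = c("grid", "corners_edges", "custom"),
                            doses1 = NULL, doses2 = NULL,
                            d1max = NULL, d2max = NULL, c1 = NULL, c2 = NULL,
                            n_mono = 8L, pairs = NULL, replicates = 1L) {
  kind <- match.arg(kind)
  stopifnot(replicates >= 1L)
  if (kind == "grid") {
    .check_doses(doses1, "doses1")
    .check_doses(doses2, "doses2")
    if (!any(doses1 == 0) || !any(doses2 == 0)) {
      stop("grid designs must include zero dose for both drugs",
           call. = FALSE)
    }
    pairs <- expand.grid(d1 = doses1, d2 = doses2, KEEP.OUT.ATTRS = FALSE)
  } else if (kind == "corners_edges") {
    for (nm in c("d1max", "d2max", "c1", "c2")) {
      .stopifnot_scalar_number(get(nm), nm, positive = TRUE)
    }
    mono1 <- dose_grid(c1 / 30, d1max, n_mono)
    mono2 <- dose_grid(c2 / 30, d2max, n_mono)
    pairs <- rbind(
      data.frame(d1 = mono1, d2 = 0),
      data.frame(d1 = 0, d2 = mono2),
      data.frame(
        d1 = c(0, d1max, 0, d1max, c1, c1, 0, d1max),
        d2 = c(0, 0, d2max, d2max, 0, d2max, c2, c2)
      )
    )
    pairs <- unique(pairs)
  } else {
    stopifnot(is.data.frame(pairs), all(c("d1", "d2") %in% names(pairs)))
    pairs <- pairs[c("d1", "d2")]
    .check_doses(pairs$d1, "pairs$d1")
    .check_doses(pairs$d2, "pairs$d2")
  }
  if (replicates > 1L) {
    pairs <- pairs[rep(seq_len(nrow(pairs)), each = replicates), ,
                   drop = FALSE]
  }
  rownames(pairs) <- NULL
  structure(
    list(kind = kind, pairs = pairs, replicates = as.integer(replicates)),
    class = "sampling_design"
  )
}

#' Log-spaced dose vector with a zero anchor
#'
#' @param dmin,dmax Positive dose range endpoints.
#' @param n Number of positive doses (log-spaced, inclusive).
#' @param include_zero Prepend a zero dose (default `TRUE`).
#' @return Numeric dose vector.
#' @export
dose_grid <- function(dmin, dmax, n, include_zero = TRUE) {
  .stopifnot_scalar_number(dmin, "dmin", positive = TRUE)
  .stopifnot_scalar_number(dmax, "dmax", positive = TRUE)
  stopifnot(dmax > dmin, n >= 2L)
  d <- 10^seq(log10(dmin), log10(dmax), length.out = n)
  if (include_zero) c(0, d) else d
}

#' Measurement-noise models for simulations
#'
#' @param kind `"none"`, `"additive_gaussian"` (adds `N(0, sigma)` in assay
#'   units) or `"proportional_gaussian"` (multiplies by `1 + N(0, sigma)`).
#'   Simulated effects are deliberately not clipped to a nominal range —
#'   real assays routinely report values outside it, and range filters are
#'   an analysis choice.
#' @param sigma Noise magnitude (assay units, or fraction for the
#'   proportional kind); `>= 0`.
#' @param seed Integer seed making draws reproducible.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(kind = c("none", "additive_gaussian",
                                 "proportional_gaussian"),
                        sigma = 0, seed = NULL) {
  kind <- match.arg(kind)
  .stopifnot_scalar_number(sigma, "sigma", nonnegative = TRUE)
  structure(list(kind = kind, sigma = sigma, seed = seed),
            class = "noise_model")
}

.apply_noise <- function(effect, noise) {
  stopifnot(inherits(noise, "noise_model"))
  if (noise$kind == "none" || noise$sigma == 0) return(effect)
  .with_seed(noise$seed, function() {
    eps <- stats::rnorm(length(effect), 0, noise$sigma)
    switch(noise$kind,
           additive_gaussian = effect + eps,
           proportional_gaussian = effect * (1 + eps))
  })
}

#' Simulate a checkerboard dataset from known surface parameters
#'
#' Evaluates the mass-action surface at every dose pair of the design and
#' applies the noise model. The generating parameters and seed are attached
#' as attributes so a simulation is fully reproducible from its output.
#'
#' @param p A [musyc_params()] object.
#' @param design A [sampling_design()].
#' @param noise A [noise_model()] (default: noiseless).
#' @return A data frame of class `dose_response` with columns `d1`, `d2`,
#'   `effect` and attributes `params`, `noise_kind`, `sigma`, `seed`.
#' @export
generate_surface_data <- function(p, design, noise = noise_model()) {
  stopifnot(inherits(p, "musyc_params"), inherits(design, "sampling_design"))
  out <- design$pairs
  out$effect <- .apply_noise(evaluate_surface(out$d1, out$d2, p), noise)
  structure(out, params = p, noise_kind = noise$kind, sigma = noise$sigma,
            seed = noise$seed, class = c("dose_response", "data.frame"))
}

#' Simulate a sham combination dataset
#'
#' A sham experiment administers one drug under two labels: the true
#' response at `(d1, d2)` is the monotherapy curve at the summed dose,
#' `H(d1 + d2)`. Feeding sham data to synergy metrics probes
#' sham compliance — dose-equivalence metrics score it additive for every
#' Hill slope, while the mass-action surface reproduces it exactly only for
#' `h = 1`.
#'
#' @param p1 A [hill_params()] object for the single drug.
#' @param design A [sampling_design()].
#' @param noise A [noise_model()].
#' @return A `dose_response` data frame as in [generate_surface_data()].
#' @export
generate_sham_data <- function(p1, design, noise = noise_model()) {
  stopifnot(inherits(p1, "hill_params"), inherits(design, "sampling_design"))
  out <- design$pairs
  out$effect <- .apply_noise(hill_1d(out$d1 + out$d2, p1), noise)
  structure(out, params = p1, noise_kind = noise$kind, sigma = noise$sigma,
            seed = noise$seed, class = c("dose_response", "data.frame"))
}

# E3 implied by a target beta given the other effects (decreasing
# orientation): beta = (min(e1,e2) - e3) / (e0 - min(e1,e2)).
.e3_from_beta <- function(beta, e0, e1, e2) {
  strongest <- min(e1, e2)
  e3 <- strongest - beta * (e0 - strongest)
  if (e3 > e0) {
    stop("beta implies E3 beyond the baseline effect window (E3 > E0)",
         call. = FALSE)
  }
  e3
}

#' Sweep synergy profiles and score them with classical metrics
#'
#' Builds a grid of synergy profiles `(log10 alpha12, log10 alpha21, beta)`
#' on fixed single-drug parameters, constructs the corresponding surface
#' for each (inverting beta to `E3`), and scores every profile with Bliss,
#' Loewe, HSA and the combination index at the EC50 dose pair `(C1, C2)`.
#' The tidy result drives masking analyses: profiles whose classical scores
#' disagree in sign with their potency/efficacy decomposition. Undefined
#' Loewe/CI cells are `NA` with their count reported in attributes.
#'
#' @param log10_alpha12,log10_alpha21,beta Numeric vectors defining the
#'   profile grid.
#' @param e0,e1,e2 Fixed effects (defaults 1, 0, 0).
#' @param c1,c2,h1,h2 Fixed single-drug potency parameters (defaults 1).
#' @param n_mono Monotherapy doses used for the combination-index
#'   median-effect fits.
#' @return A data frame with one row per profile: the profile coordinates,
#'   `e3`, and columns `bliss`, `loewe`, `hsa`, `ci`,
#'   `neg_log10_loewe`, `neg_log10_ci`.
#' @export
sweep_profiles <- function(log10_alpha12, log10_alpha21, beta,
                           e0 = 1, e1 = 0, e2 = 0,
                           c1 = 1, c2 = 1, h1 = 1, h2 = 1, n_mono = 9L) {
  grid <- expand.grid(log10_alpha12 = log10_alpha12,
                      log10_alpha21 = log10_alpha21,
                      beta = beta, KEEP.OUT.ATTRS = FALSE)
  # shared monotherapy data for the median-effect fits (exact, noiseless)
  mono1 <- dose_grid(c1 / 100, c1 * 100, n_mono, include_zero = FALSE)
  mono2 <- dose_grid(c2 / 100, c2 * 100, n_mono, include_zero = FALSE)
  me_data <- rbind(
    data.frame(d1 = mono1,
               d2 = 0,
               effect = hill_1d(mono1, hill_params(e0, e1, c1, h1))),
    data.frame(d1 = 0,
               d2 = mono2,
               effect = hill_1d(mono2, hill_params(e0, e2, c2, h2)))
  )
  score_one <- function(la12, la21, b) {
    e3 <- .e3_from_beta(b, e0, e1, e2)
    p <- musyc_params(e0, e1, e2, e3, c1, c2, h1, h2,
                      alpha12 = 10^la12, alpha21 = 10^la21)
    at <- c(c1, c2)
    E <- evaluate_surface(at[1], at[2], p)
    c(e3 = e3,
      bliss = bliss_score(p, at),
      loewe = loewe_index(p, at),
      hsa = hsa_score(p, at),
      ci = as.numeric(combination_index(me_data, at, effect = E)))
  }
  scores <- t(mapply(score_one, grid$log10_alpha12, grid$log10_alpha21,
                     grid$beta))
  out <- cbind(grid, as.data.frame(scores))
  out$neg_log10_loewe <- neg_log10_score(out$loewe)
  out$neg_log10_ci <- neg_log10_score(out$ci)
  structure(out,
            n_loewe_undefined = sum(is.na(out$loewe)),
            n_ci_undefined = sum(is.na(out$ci)))
}
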
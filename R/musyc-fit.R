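#' Fitting configuration
#'
#' Options controlling [fit_musyc()]. Effect bounds are assay-specific: for
#' normalized viability screens a near-pinned baseline such as
#' `e0_bounds = c(0.99, 1.01)` with plateaus in `[0, 2.5]` is typical;
#' defaults are unbounded so arbitrary effect scales work out of the box.
#'
#' @param e0_bounds,e1_bounds,e2_bounds,e3_bounds Length-2 bounds on the
#'   state effects during the 2D fit (and, for `e0`/`e1`/`e2`, the seeding
#'   monotherapy fits).
#' @param orientation `"decreasing"` (viability-like) or `"increasing"`;
#'   controls which plateau counts as the strongest single agent.
#' @param gamma_enabled Fit the cooperativity-synergy parameters
#'   `gamma12`, `gamma21`? Default `FALSE` (fixed at 1): in practice they
#'   rarely improve fit quality and the model is nested, so disabling them
#'   loses nothing on `gamma = 1` data.
#' @param log_alpha_bounds Bounds on `log10(alpha)`, default `c(-4, 4)`.
#' @param log_gamma_bounds Bounds on `log10(gamma)` when enabled.
#' @param mc_samples Number of Monte-Carlo resamples for confidence
#'   intervals, default 100.
#' @param seed Integer seed for the Monte-Carlo noise stream.
#' @param r2_threshold QC threshold on R-squared, default 0.7.
#' @param stage1_se_mult Multiplier on stage-1 standard errors when deriving
#'   2D-fit bounds for the shared parameters, default 3.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(e0_bounds = c(-Inf, Inf), e1_bounds = c(-Inf, Inf),
                       e2_bounds = c(-Inf, Inf), e3_bounds = c(-Inf, Inf),
                       orientation = c("decreasing", "increasing"),
                       gamma_enabled = FALSE,
                       log_alpha_bounds = c(-4, 4),
                       log_gamma_bounds = c(-2, 2),
                       mc_samples = 100L, seed = NULL,
                       r2_threshold = 0.7, stage1_se_mult = 3) {
  orientation <- match.arg(orientation)
  for (b in list(e0_bounds, e1_bounds, e2_bounds, e3_bounds,
                 log_alpha_bounds, log_gamma_bounds)) {
    stopifnot(is.numeric(b), length(b) == 2L, b[1] <= b[2])
  }
  stopifnot(mc_samples >= 1L)
  structure(
    list(e0_bounds = e0_bounds, e1_bounds = e1_bounds,
         e2_bounds = e2_bounds, e3_bounds = e3_bounds,
         orientation = orientation, gamma_enabled = isTRUE(gamma_enabled),
         log_alpha_bounds = log_alpha_bounds,
         log_gamma_bounds = log_gamma_bounds,
         mc_samples = as.integer(mc_samples), seed = seed,
         r2_threshold = r2_threshold, stage1_se_mult = stage1_se_mult),
    class = "fit_config"
  )
}

# Internal parameter vector of the 2D fit (order matters):
# e0, e1, e2, e3 on the effect scale; lc1, lc2, lh1, lh2, la12, la21
# (and lg12, lg21 when gamma is fitted) as log10 values.
.theta_names <- function(gamma_enabled) {
  nm <- c("e0", "e1", "e2", "e3", "lc1", "lc2", "lh1", "lh2", "la12", "la21")
  if (gamma_enabled) nm <- c(nm, "lg12", "lg21")
  nm
}

.theta_to_params <- function(th, gamma_enabled) {
  musyc_params(
    e0 = th[["e0"]], e1 = th[["e1"]], e2 = th[["e2"]], e3 = th[["e3"]],
    c1 = 10^th[["lc1"]], c2 = 10^th[["lc2"]],
    h1 = 10^th[["lh1"]], h2 = 10^th[["lh2"]],
    alpha12 = 10^th[["la12"]], alpha21 = 10^th[["la21"]],
    gamma12 = if (gamma_enabled) 10^th[["lg12"]] else 1,
    gamma21 = if (gamma_enabled) 10^th[["lg21"]] else 1
  )
}

# Unvalidated parameter list for the optimizer hot path; fields mirror
# musyc_params() exactly.
.theta_to_params_fast <- function(th, gamma_enabled) {
  structure(
    list(e0 = th[[1]], e1 = th[[2]], e2 = th[[3]], e3 = th[[4]],
         c1 = 10^th[[5]], c2 = 10^th[[6]], h1 = 10^th[[7]], h2 = 10^th[[8]],
         alpha12 = 10^th[[9]], alpha21 = 10^th[[10]],
         gamma12 = if (gamma_enabled) 10^th[[11]] else 1,
         gamma21 = if (gamma_enabled) 10^th[[12]] else 1,
         r1 = 100, r2 = 100),
    class = "musyc_params"
  )
}

.musyc_residuals <- function(th, d1, d2, effect, gamma_enabled) {
  p <- .theta_to_params_fast(th, gamma_enabled)
  s <- .states_vec(d1, d2, p)
  effect - (p$e0 * s$U + p$e1 * s$A1 + p$e2 * s$A2 + p$e3 * s$A12)
}

.run_nlsfit <- function(th0, lower, upper, d1, d2, effect, gamma_enabled,
                        ftol = 1e-13, maxiter = 500) {
  tryCatch(
    minpack.lm::nls.lm(
      par = th0, lower = lower, upper = upper,
      fn = .musyc_residuals, d1 = d1, d2 = d2, effect = effect,
      gamma_enabled = gamma_enabled,
      jac = function(th, d1, d2, effect, gamma_enabled) {
        .num_jac(.musyc_residuals, th, d1 = d1, d2 = d2, effect = effect,
                 gamma_enabled = gamma_enabled)
      },
      control = minpack.lm::nls.lm.control(
        maxiter = maxiter, ftol = ftol, ptol = ftol
      )
    ),
    error = function(e) NULL
  )
}

#' Goodness of fit of a surface to dose-response data
#'
#' @param data A dose-response data frame with columns `d1`, `d2`, `effect`
#'   (see [read_dose_response_csv()] / [generate_surface_data()]).
#' @param p A [musyc_params()] object.
#' @return A list with `r_squared` (`1 - SS_res/SS_tot`; `NA` for
#'   zero-variance effects) and `rms` (root-mean-square residual).
#' @export
goodness_of_fit <- function(data, p) {
  data <- .as_dose_response(data)
  stopifnot(nrow(data) >= 2L)
  pred <- evaluate_surface(data$d1, data$d2, p)
  res <- data$effect - pred
  ss_tot <- sum((data$effect - mean(data$effect))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - sum(res^2) / ss_tot
  list(r_squared = r2, rms = sqrt(mean(res^2)))
}

#' Fit the two-dimensional Hill surface to checkerboard data
#'
#' The staged pipeline:
#'
#' 1. **Monotherapy seeding.** The four-parameter Hill equation is fit to
#'    each drug's single-agent rows ([fit_hill_1d()]), giving estimates and
#'    standard errors for `E0, E1, E2, C1, C2, h1, h2`.
#' 2. **Bounded 2D fit.** The full surface is fit by bounded nonlinear least
#'    squares, initialized at the stage-1 estimates with
#'    `E3 = min(E1, E2)` and `alpha = gamma = 1`. Shared parameters are
#'    bounded to their stage-1 estimate plus/minus `stage1_se_mult` standard
#'    errors (intersected with the configured effect bounds);
#'    `log10(alpha)` is bounded to `[-4, 4]`. EC50s and slopes are
#'    parameterized as log10 values to tame the slope/EC50 collinearity.
#' 3. **Monte-Carlo uncertainty.** [monte_carlo_ci()] refits
#'    noise-perturbed model predictions to obtain asymmetric 95% percentile
#'    intervals per parameter.
#'
#' QC passes when R-squared exceeds the configured threshold and both fitted
#' EC50s lie below the maximum tested dose of their drug; otherwise the
#' result is flagged with reasons and should be excluded from downstream
#' synergy analysis.
#'
#' @param data Dose-response data: a data frame with columns `d1`, `d2`,
#'   `effect` containing monotherapy rows for both drugs (`d2 == 0` and
#'   `d1 == 0`) and at least one interior combination row.
#' @param config A [fit_config()].
#' @return An object of class `musyc_fit`: list with `params`
#'   ([musyc_params()]), `profile` (beta and log10 alpha/gamma with CI
#'   bounds), `ci` (data frame of per-parameter estimate/lower/upper),
#'   `r_squared`, `rms`, `qc_pass`, `qc_reasons`, `stage1`, `mc` details and
#'   the `seed` used.
#' @export
fit_musyc <- function(data, config = fit_config()) {
  stopifnot(inherits(config, "fit_config"))
  data <- .as_dose_response(data)
  qc_fail <- function(reasons, stage1 = NULL) {
    structure(
      list(params = NULL, profile = NULL, ci = NULL,
           r_squared = NA_real_, rms = NA_real_,
           qc_pass = FALSE, qc_reasons = reasons, stage1 = stage1,
           mc = NULL, seed = config$seed, config = config),
      class = "musyc_fit"
    )
  }

  mono1 <- data[data$d2 == 0, ]
  mono2 <- data[data$d1 == 0, ]
  f1 <- fit_hill_1d(mono1$d1, mono1$effect, config$e0_bounds, config$e1_bounds)
  f2 <- fit_hill_1d(mono2$d2, mono2$effect, config$e0_bounds, config$e2_bounds)
  stage1 <- list(drug1 = f1, drug2 = f2)
  if (!f1$converged || !f2$converged) {
    why <- c(
      if (!f1$converged) paste0("monotherapy fit failed (drug 1): ", f1$reason),
      if (!f2$converged) paste0("monotherapy fit failed (drug 2): ", f2$reason)
    )
    return(qc_fail(why, stage1))
  }

  k <- config$stage1_se_mult
  band <- function(est, se, cfg_lo, cfg_hi) {
    lo <- max(est - k * se, cfg_lo)
    hi <- min(est + k * se, cfg_hi)
    if (!is.finite(lo) && !is.finite(hi)) return(c(cfg_lo, cfg_hi))
    if (lo > hi) c(cfg_lo, cfg_hi) else c(lo, hi)  # empty intersection
  }
  e0_est <- mean(c(f1$theta[["e0"]], f2$theta[["e0"]]))
  e0_se <- max(f1$se[["e0"]], f2$se[["e0"]])
  b_e0 <- band(e0_est, e0_se, config$e0_bounds[1], config$e0_bounds[2])
  b_e1 <- band(f1$theta[["emax"]], f1$se[["emax"]],
               config$e1_bounds[1], config$e1_bounds[2])
  b_e2 <- band(f2$theta[["emax"]], f2$se[["emax"]],
               config$e2_bounds[1], config$e2_bounds[2])
  b_lc1 <- band(f1$theta[["lc"]], f1$se[["lc"]], -Inf, Inf)
  b_lc2 <- band(f2$theta[["lc"]], f2$se[["lc"]], -Inf, Inf)
  b_lh1 <- band(f1$theta[["lh"]], f1$se[["lh"]], -3, 3)
  b_lh2 <- band(f2$theta[["lh"]], f2$se[["lh"]], -3, 3)

  ge <- config$gamma_enabled
  e3_init <- if (config$orientation == "decreasing") {
    min(f1$theta[["emax"]], f2$theta[["emax"]])
  } else {
    max(f1$theta[["emax"]], f2$theta[["emax"]])
  }
  th0 <- c(
    e0 = e0_est, e1 = f1$theta[["emax"]], e2 = f2$theta[["emax"]],
    e3 = e3_init,
    lc1 = f1$theta[["lc"]], lc2 = f2$theta[["lc"]],
    lh1 = f1$theta[["lh"]], lh2 = f2$theta[["lh"]],
    la12 = 0, la21 = 0
  )
  lower <- c(b_e0[1], b_e1[1], b_e2[1], config$e3_bounds[1],
             b_lc1[1], b_lc2[1], b_lh1[1], b_lh2[1],
             config$log_alpha_bounds[1], config$log_alpha_bounds[1])
  upper <- c(b_e0[2], b_e1[2], b_e2[2], config$e3_bounds[2],
             b_lc1[2], b_lc2[2], b_lh1[2], b_lh2[2],
             config$log_alpha_bounds[2], config$log_alpha_bounds[2])
  if (ge) {
    th0 <- c(th0, lg12 = 0, lg21 = 0)
    lower <- c(lower, rep(config$log_gamma_bounds[1], 2))
    upper <- c(upper, rep(config$log_gamma_bounds[2], 2))
  }
  names(lower) <- names(upper) <- .theta_names(ge)
  th0 <- pmin(pmax(th0, lower), upper)

  fit <- .run_nlsfit(th0, lower, upper, data$d1, data$d2, data$effect, ge)
  if (is.null(fit) || !fit$info %in% 1:4) {
    return(qc_fail("2D optimizer failed to converge", stage1))
  }
  th <- fit$par
  params <- .theta_to_params(th, ge)
  gof <- goodness_of_fit(data, params)

  qc_reasons <- character()
  if (!is.finite(gof$r_squared) || gof$r_squared <= config$r2_threshold) {
    qc_reasons <- c(qc_reasons,
                    sprintf("R-squared %.3f below threshold %.2f",
                            gof$r_squared, config$r2_threshold))
  }
  if (params$c1 >= max(data$d1)) {
    qc_reasons <- c(qc_reasons, "fitted C1 at or above maximum tested d1")
  }
  if (params$c2 >= max(data$d2)) {
    qc_reasons <- c(qc_reasons, "fitted C2 at or above maximum tested d2")
  }

  mc <- monte_carlo_ci(data, best_theta = th, lower = lower, upper = upper,
                       rms = gof$rms, gamma_enabled = ge,
                       n_samples = config$mc_samples, seed = config$seed,
                       orientation = config$orientation)
  qc_reasons <- c(qc_reasons, mc$qc_reasons)

  structure(
    list(params = params, profile = mc$profile, ci = mc$ci,
         r_squared = gof$r_squared, rms = gof$rms,
         qc_pass = length(qc_reasons) == 0L, qc_reasons = qc_reasons,
         stage1 = stage1, mc = mc[c("n_requested", "n_ok")],
         seed = config$seed, config = config),
    class = "musyc_fit"
  )
}

# Natural-scale report row names for a theta vector.
.report_params <- function(th, ge, orientation) {
  out <- c(
    E0 = th[["e0"]], E1 = th[["e1"]], E2 = th[["e2"]], E3 = th[["e3"]],
    C1 = 10^th[["lc1"]], C2 = 10^th[["lc2"]],
    h1 = 10^th[["lh1"]], h2 = 10^th[["lh2"]],
    log10_alpha12 = th[["la12"]], log10_alpha21 = th[["la21"]]
  )
  if (ge) {
    out <- c(out, log10_gamma12 = th[["lg12"]], log10_gamma21 = th[["lg21"]])
  }
  c(out, beta = .beta_from_effects(th[["e0"]], th[["e1"]], th[["e2"]],
                                   th[["e3"]], orientation))
}

#' Monte-Carlo percentile confidence intervals for a surface fit
#'
#' Implements the Motulsky-Christopoulos Monte-Carlo scheme: Gaussian noise
#' `N(0, sigma)` with `sigma` equal to the root-mean-square residual of the
#' best fit is added to the best-fit model predictions at the observed
#' doses, and the surface is refit starting from the best-fit parameters.
#' Repeating this `n_samples` times yields an ensemble of parameter vectors
#' whose spread estimates the fit uncertainty while respecting the strong
#' slope/EC50/alpha collinearities of the 2D Hill equation; the resulting
#' intervals are asymmetric (e.g. Hill-slope uncertainty is log-normal-like).
#'
#' The 95% interval for each parameter takes the k-th smallest and k-th
#' largest ensemble values with `k = ceiling(0.025 * n)` (order-statistic
#' trimming, n = surviving refits). Refits that fail to converge are dropped;
#' if more than half fail a `wide-CI` QC reason is raised. Intervals are
#' widened, if needed, to contain the point estimate.
#'
#' This function is called by [fit_musyc()]; calling it directly requires
#' the internal parameterization documented there.
#'
#' @param data The dose-response data frame used for the fit.
#' @param best_theta Named best-fit parameter vector in the internal
#'   (log10-transformed) parameterization.
#' @param lower,upper Bounds used for the refits (same as the main fit).
#' @param rms Root-mean-square residual of the best fit (the noise sigma).
#' @param gamma_enabled Whether gamma parameters are part of `best_theta`.
#' @param n_samples Number of Monte-Carlo samples.
#' @param seed Integer seed; the single stream drives all noise draws.
#' @param orientation Effect orientation, for the derived beta.
#' @return List with `ci` (data frame: parameter, estimate, lower, upper),
#'   `profile`, `ensemble` (matrix of refit parameter vectors on the report
#'   scale), `n_requested`, `n_ok`, `qc_reasons`.
#' @export
monte_carlo_ci <- function(data, best_theta, lower, upper, rms,
                           gamma_enabled, n_samples = 100L, seed = NULL,
                           orientation = "decreasing") {
  data <- .as_dose_response(data)
  params <- .theta_to_params(best_theta, gamma_enabled)
  pred <- evaluate_surface(data$d1, data$d2, params)
  n_obs <- nrow(data)

  draws <- .with_seed(seed, function() {
    matrix(stats::rnorm(n_obs * n_samples, mean = 0, sd = rms),
           nrow = n_obs, ncol = n_samples)
  })
  keep <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    refit <- .run_nlsfit(best_theta, lower, upper, data$d1, data$d2,
                         pred + draws[, i], gamma_enabled,
                         ftol = 1e-10, maxiter = 200)
    if (!is.null(refit) && refit$info %in% 1:4 && all(is.finite(refit$par))) {
      keep[[i]] <- .report_params(refit$par, gamma_enabled, orientation)
    }
  }
  keep <- keep[!vapply(keep, is.null, logical(1))]
  n_ok <- length(keep)
  qc_reasons <- character()
  if (n_ok < n_samples / 2) {
    qc_reasons <- "wide-CI: more than half of Monte-Carlo refits failed"
  }

  est <- .report_params(best_theta, gamma_enabled, orientation)
  if (n_ok >= 2L) {
    ens <- do.call(rbind, keep)
    kk <- ceiling(0.025 * n_ok)
    lo <- apply(ens, 2, function(x) sort(x)[kk])
    hi <- apply(ens, 2, function(x) sort(x)[n_ok + 1L - kk])
  } else {
    ens <- NULL
    lo <- hi <- est
  }
  lo <- pmin(lo, est, na.rm = TRUE)
  hi <- pmax(hi, est, na.rm = TRUE)
  ci <- data.frame(parameter = names(est), estimate = unname(est),
                   lower = unname(lo), upper = unname(hi),
                   stringsAsFactors = FALSE)
  pick <- function(nm) {
    i <- match(nm, ci$parameter)
    if (is.na(i)) NULL else as.list(ci[i, c("estimate", "lower", "upper")])
  }
  profile <- list(
    beta = pick("beta"),
    log10_alpha12 = pick("log10_alpha12"),
    log10_alpha21 = pick("log10_alpha21"),
    log10_gamma12 = pick("log10_gamma12"),
    log10_gamma21 = pick("log10_gamma21")
  )
  list(ci = ci, profile = profile, ensemble = ens,
       n_requested = n_samples, n_ok = n_ok, qc_reasons = qc_reasons)
}

#' @export
print.musyc_fit <- function(x, ...) {
  cat("MuSyC surface fit\n")
  if (is.null(x$params)) {
    cat("  FAILED:", paste(x$qc_reasons, collapse = "; "), "\n")
    return(invisible(x))
  }
  cat(sprintf("  R-squared = %.4f, RMS = %.4g, QC %s\n",
              x$r_squared, x$rms,
              if (x$qc_pass) "pass" else
                paste0("FAIL (", paste(x$qc_reasons, collapse = "; "), ")")))
  print(x$ci, row.names = FALSE, digits = 4)
  invisible(x)
}
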
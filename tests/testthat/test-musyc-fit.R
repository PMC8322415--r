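test_that("goodness_of_fit computes R-squared and RMS as defined", {
  p <- ref_params()
  dat <- generate_surface_data(p, ref_design())
  g <- goodness_of_fit(dat, p)
  expect_equal(g$r_squared, 1)
  expect_equal(g$rms, 0)
  shifted <- dat
  shifted$effect <- shifted$effect + 0.3
  expect_equal(goodness_of_fit(shifted, p)$rms, 0.3)
  flat <- dat
  flat$effect <- rep(0.4, nrow(dat))
  expect_true(is.na(goodness_of_fit(flat, p)$r_squared))
})

test_that("fit_musyc recovers generating parameters from a noiseless grid", {
  dat <- generate_surface_data(ref_params(), ref_design())
  fit <- fit_musyc(dat, fit_config(mc_samples = 5, seed = 1))
  expect_true(fit$qc_pass)
  expect_gt(fit$r_squared, 1 - 1e-10)
  ci <- fit$ci
  rownames(ci) <- ci$parameter
  truth <- ref_truth()
  for (nm in names(truth)) {
    expect_equal(ci[nm, "estimate"], truth[[nm]], tolerance = 1e-3,
                 label = paste("estimate of", nm))
  }
  # near-zero residuals imply near-zero Monte-Carlo interval widths
  widths <- ci$upper - ci$lower
  expect_lt(max(widths / pmax(abs(ci$estimate), 1)), 1e-2)
  # CI ordering invariant
  expect_true(all(ci$lower <= ci$estimate & ci$estimate <= ci$upper))
})

test_that("Monte-Carlo confidence intervals are deterministic under a seed
          and asymmetric under noise", {
  dat <- generate_surface_data(
    ref_params(), ref_design(),
    noise_model("additive_gaussian", 0.02, seed = 55)
  )
  f1 <- fit_musyc(dat, fit_config(mc_samples = 40, seed = 9))
  f2 <- fit_musyc(dat, fit_config(mc_samples = 40, seed = 9))
  expect_identical(f1$ci, f2$ci)
  f3 <- fit_musyc(dat, fit_config(mc_samples = 40, seed = 10))
  expect_false(identical(f3$ci, f1$ci))
  # Hill-slope intervals are log-normal-like: not symmetric about the point
  ci <- f1$ci
  rownames(ci) <- ci$parameter
  up <- ci["h1", "upper"] - ci["h1", "estimate"]
  lo <- ci["h1", "estimate"] - ci["h1", "lower"]
  expect_false(isTRUE(all.equal(up, lo)))
})

test_that("QC flags truncated dosing and degenerate inputs", {
  # EC50 of drug 1 beyond the tested range
  p <- musyc_params(1, 0.3, 0.5, 0.1, c1 = 20, c2 = 1, h1 = 1, h2 = 1)
  des <- sampling_design("grid", doses1 = dose_grid(0.1, 10, 7),
                         doses2 = dose_grid(0.01, 100, 7))
  fit <- fit_musyc(generate_surface_data(p, des),
                   fit_config(mc_samples = 2, seed = 1))
  expect_false(fit$qc_pass)
  expect_true(any(grepl("C1 at or above", fit$qc_reasons)))
  # flat monotherapy -> stage-1 failure propagates
  flat <- generate_surface_data(ref_params(), ref_design())
  flat$effect <- rep(1, nrow(flat))
  ffit <- fit_musyc(flat, fit_config(mc_samples = 2, seed = 1))
  expect_false(ffit$qc_pass)
  expect_true(any(grepl("monotherapy fit failed", ffit$qc_reasons)))
})

test_that("gamma fitting nests the default model on gamma = 1 data", {
  dat <- generate_surface_data(ref_params(), ref_design())
  f0 <- fit_musyc(dat, fit_config(mc_samples = 2, seed = 3))
  fg <- fit_musyc(dat, fit_config(mc_samples = 2, seed = 3,
                                  gamma_enabled = TRUE))
  expect_true(fg$qc_pass)
  grid <- expand.grid(d1 = dose_grid(0.05, 50, 5, include_zero = FALSE),
                      d2 = dose_grid(0.05, 50, 5, include_zero = FALSE))
  expect_equal(evaluate_surface(grid$d1, grid$d2, fg$params),
               evaluate_surface(grid$d1, grid$d2, f0$params),
               tolerance = 1e-5)
  expect_equal(fg$params$gamma12, 1, tolerance = 1e-3)
})

test_that("potency synergy is recovered across noise kinds and designs", {
  p <- ref_params()
  la12_err <- function(noise) {
    dat <- generate_surface_data(p, ref_design(), noise)
    fit <- fit_musyc(dat, fit_config(mc_samples = 2, seed = 2))
    abs(fit$ci$estimate[fit$ci$parameter == "log10_alpha12"] - log10(3))
  }
  # 2% additive noise on the 8x8 checkerboard: median potency-synergy error
  # below 0.2 decades
  errs_add <- vapply(1:9, function(s) {
    la12_err(noise_model("additive_gaussian", 0.02, seed = 100 + s))
  }, numeric(1))
  expect_lt(median(errs_add), 0.2)
  # proportional noise of comparable magnitude behaves similarly
  errs_prop <- vapply(1:5, function(s) {
    la12_err(noise_model("proportional_gaussian", 0.03, seed = 200 + s))
  }, numeric(1))
  expect_lt(median(errs_prop), 0.3)
  # the economical corners-and-edges design also identifies the parameters
  ce <- sampling_design("corners_edges", d1max = 100, d2max = 100,
                        c1 = 1, c2 = 1, n_mono = 8)
  fit_ce <- fit_musyc(generate_surface_data(p, ce),
                      fit_config(mc_samples = 2, seed = 4))
  ci <- fit_ce$ci
  rownames(ci) <- ci$parameter
  expect_equal(ci["log10_alpha12", "estimate"], log10(3), tolerance = 0.05)
  expect_equal(ci["E3", "estimate"], 0.1, tolerance = 0.01)
})

test_that("percentile intervals use the prescribed order statistics", {
  # with n surviving refits the bounds are the k-th smallest/largest values,
  # k = ceiling(0.025 n); check against a hand-built ensemble via the
  # exported monte_carlo_ci on deterministic (rms = 0) draws plus a direct
  # order-statistic computation on a noisy ensemble
  dat <- generate_surface_data(
    ref_params(), ref_design(),
    noise_model("additive_gaussian", 0.02, seed = 77)
  )
  fit <- fit_musyc(dat, fit_config(mc_samples = 40, seed = 6))
  mcfit <- fit_musyc(dat, fit_config(mc_samples = 40, seed = 6))
  expect_identical(fit$ci, mcfit$ci)
  # reproduce the interval from the ensemble returned by monte_carlo_ci
  p <- fit$params
  th <- c(e0 = p$e0, e1 = p$e1, e2 = p$e2, e3 = p$e3,
          lc1 = log10(p$c1), lc2 = log10(p$c2),
          lh1 = log10(p$h1), lh2 = log10(p$h2),
          la12 = log10(p$alpha12), la21 = log10(p$alpha21))
  lower <- c(rep(-Inf, 6), -3, -3, -4, -4)
  upper <- c(rep(Inf, 6), 3, 3, 4, 4)
  mc <- monte_carlo_ci(dat, th, lower, upper, rms = fit$rms,
                       gamma_enabled = FALSE, n_samples = 40, seed = 6)
  k <- ceiling(0.025 * mc$n_ok)
  for (j in c("C1", "h1", "log10_alpha12")) {
    col <- mc$ensemble[, j]
    i <- match(j, mc$ci$parameter)
    expect_equal(mc$ci$lower[i], min(sort(col)[k], mc$ci$estimate[i]))
    expect_equal(mc$ci$upper[i],
                 max(sort(col)[mc$n_ok + 1 - k], mc$ci$estimate[i]))
  }
})
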
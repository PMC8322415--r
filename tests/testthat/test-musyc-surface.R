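test_that("transition matrix has the conservation structure and symmetry", {
  p <- ref_params()
  m0 <- build_transition_matrix(0, 0, p)
  expect_equal(unname(solve(m0, c(0, 0, 0, 1))), c(1, 0, 0, 0))
  # column sums of the three balance rows reproduce the (negated) fourth
  # balance equation: the dynamic system is rank 3
  set.seed(11)
  for (i in 1:5) {
    q <- rand_params()
    d1 <- 10^runif(1, -2, 2); d2 <- 10^runif(1, -2, 2)
    m <- build_transition_matrix(d1, d2, q)
    g12 <- q$r2^q$gamma12 * (q$alpha12 * d2)^(q$gamma12 * q$h2)
    g21 <- q$r1^q$gamma21 * (q$alpha21 * d1)^(q$gamma21 * q$h1)
    rm1g <- (q$r1 * q$c1^q$h1)^q$gamma21
    rm2g <- (q$r2 * q$c2^q$h2)^q$gamma12
    dA12 <- c(0, g12, g21, -(rm1g + rm2g))  # dA12/dt coefficients
    expect_equal(unname(colSums(m[1:3, ])), -dA12, tolerance = 1e-12)
  }
  # swapping drug labels leaves a symmetric system invariant
  ps <- musyc_params(1, 0.3, 0.3, 0.1, 1, 1, 2, 2, alpha12 = 1, alpha21 = 1)
  m <- build_transition_matrix(1, 1, ps)
  perm <- c(1, 3, 2, 4)
  expect_equal(unname(m[perm, perm]), unname(m), tolerance = 1e-12)
})

test_that("state populations are conserved, bounded, and hit boundary limits", {
  p <- ref_params()
  expect_equal(solve_state_populations(0, 0, p),
               c(U = 1, A1 = 0, A2 = 0, A12 = 0))
  s <- solve_state_populations(1e9, 0, p)
  expect_equal(unname(s[["A1"]]), 1, tolerance = 1e-6)
  set.seed(12)
  for (i in 1:20) {
    q <- rand_params()
    s <- solve_state_populations(10^runif(1, -3, 3), 10^runif(1, -3, 3), q)
    expect_true(all(s >= 0 & s <= 1))
    expect_lt(abs(sum(s) - 1), 1e-9)
  }
})

test_that("scalar solve and vectorized surface evaluation agree", {
  set.seed(13)
  for (i in 1:10) {
    q <- rand_params()
    d1 <- 10^runif(4, -2, 2); d2 <- 10^runif(4, -2, 2)
    vec <- evaluate_surface(d1, d2, q)
    sca <- vapply(seq_along(d1), function(j) {
      s <- solve_state_populations(d1[j], d2[j], q)
      sum(s * c(q$e0, q$e1, q$e2, q$e3))
    }, numeric(1))
    expect_equal(vec, sca, tolerance = 1e-10)
  }
})

test_that("surface reduces to the monotherapy Hill curves on the axes and to
          the shifted Hill curve at saturating co-drug", {
  p <- musyc_params(1, 0.3, 0.5, 0.1, c1 = 2, c2 = 0.5, h1 = 1.5, h2 = 0.8,
                    alpha12 = 3, alpha21 = 0.5, gamma12 = 1.2, gamma21 = 0.7)
  expect_equal(evaluate_surface(0, 0, p), 1)
  set.seed(14)
  d <- 10^runif(10, -3, 3)
  expect_equal(evaluate_surface(d, 0 * d, p),
               hill_1d(d, hill_params(1, 0.3, 2, 1.5)), tolerance = 1e-12)
  expect_equal(evaluate_surface(0 * d, d, p),
               hill_1d(d, hill_params(1, 0.5, 0.5, 0.8)), tolerance = 1e-12)
  # d1 -> infinity: 1D Hill in d2 with plateau E1 -> E3, EC50 C2/alpha12,
  # slope gamma12 * h2
  d2 <- 10^seq(-2, 2, length.out = 9)
  lim <- 0.1 + (0.3 - 0.1) / (1 + (3 * d2 / 0.5)^(1.2 * 0.8))
  expect_equal(evaluate_surface(rep(1e6 * p$c1, 9), d2, p), lim,
               tolerance = 1e-4)
})

test_that("multiplicative-survival parameters make the surface a product of
          monotherapy curves", {
  p <- musyc_params(1, 0.5, 0.5, 0.25, 1, 1, 1, 1)
  expect_equal(evaluate_surface(1, 1, p), 0.5625)  # 0.75 * 0.75
  set.seed(15)
  e1 <- runif(1, 0.1, 0.9); e2 <- runif(1, 0.1, 0.9)
  q <- musyc_params(1, e1, e2, e1 * e2, 0.7, 2.1, 1.4, 0.9)
  d1 <- 10^runif(15, -2, 2); d2 <- 10^runif(15, -2, 2)
  expect_equal(evaluate_surface(d1, d2, q),
               hill_1d(d1, hill_params(1, e1, 0.7, 1.4)) *
                 hill_1d(d2, hill_params(1, e2, 2.1, 0.9)),
               tolerance = 1e-9)
})

test_that("beta measures the gain over the strongest single agent", {
  expect_equal(compute_beta(musyc_params(1, 0.5, 0.5, 0.25, 1, 1, 1, 1)), 0.5)
  expect_equal(compute_beta(musyc_params(1, 0.4, 0.6, 0.4, 1, 1, 1, 1)), 0)
  expect_equal(compute_beta(musyc_params(1, 0.4, 0.6, 0.5, 1, 1, 1, 1)),
               -1 / 6)
  # increasing orientation mirrors the decreasing convention
  expect_equal(
    compute_beta(musyc_params(0, 0.6, 0.4, 0.8, 1, 1, 1, 1),
                 orientation = "increasing"), 1 / 3)
  expect_true(is.na(compute_beta(musyc_params(0.5, 0.5, 0.8, 0.2, 1, 1, 1, 1))))
})

test_that("sham surfaces agree exactly iff the Hill slope is one", {
  expect_equal(sham_surface_musyc(1, 1, 1, 3, 1, 0), 1 / 3)
  expect_equal(sham_surface_true(1, 1, 1, 3, 1, 0), 1 / 9)
  g <- 10^seq(log10(0.1), log10(10), length.out = 25)
  grid <- expand.grid(d1 = g, d2 = g)
  dmax <- function(h) {
    max(abs(sham_surface_musyc(grid$d1, grid$d2, 1, h, 1, 0) -
              sham_surface_true(grid$d1, grid$d2, 1, h, 1, 0)))
  }
  expect_lt(dmax(1), 1e-9)
  for (h in c(0.5, 2, 3)) expect_gt(dmax(h), 0.05)
  # d2 = 0 restriction is the plain monotherapy curve
  expect_equal(sham_surface_true(g, 0, 1, 2.5, 1, 0.2),
               hill_1d(g, hill_params(1, 0.2, 1, 2.5)))
  # and the model sham form is the alpha = 0 surface with shared parameters
  p0 <- musyc_params(1, 0.2, 0.2, 0.2, 1, 1, 2, 2, alpha12 = 0, alpha21 = 0)
  expect_equal(evaluate_surface(grid$d1, grid$d2, p0),
               sham_surface_musyc(grid$d1, grid$d2, 1, 2, 1, 0.2),
               tolerance = 1e-9)
})

test_that("the two multi-drug affected/unaffected ratios agree only at h = 1", {
  expect_equal(ci_affected_ratio_invalid(c(1, 1), c(1, 1), 1), 2)
  expect_equal(ci_affected_ratio_correct(c(1, 1), c(1, 1), c(1, 1)), 2)
  expect_equal(ci_affected_ratio_invalid(c(1, 1), c(1, 1), 2), 4)
  expect_equal(ci_affected_ratio_correct(c(1, 1), c(1, 1), c(2, 2)), 2)
  # single drug: both reduce to the median-effect ratio
  expect_equal(ci_affected_ratio_invalid(3, 2, 1.7),
               ci_affected_ratio_correct(3, 2, 1.7))
})

test_that("synergy parameter count follows the hyper-cube scaling", {
  expect_identical(synergy_param_count(2), 5L)
  expect_identical(synergy_param_count(3), 22L)
  # N = 2 enumeration: alpha12, alpha21, beta, gamma12, gamma21
  expect_identical(synergy_param_count(2),
                   length(c("alpha12", "alpha21", "beta",
                            "gamma12", "gamma21")))
  expect_error(synergy_param_count(1), ">= 2")
  expect_error(synergy_param_count(2.5), ">= 2")
})

test_that("algebraic steady state matches the integrated ODE system", {
  skip_if_not_installed("deSolve")
  p <- musyc_params(1, 0.3, 0.5, 0.1, 1, 1, 1, 1, alpha12 = 1, alpha21 = 1)
  expect_equal(evaluate_surface(1, 1, p), ode_steady_effect(1, 1, p),
               tolerance = 1e-6)
  set.seed(16)
  for (i in 1:5) {
    q <- rand_params()
    d1 <- 10^runif(1, -1, 1) * q$c1
    d2 <- 10^runif(1, -1, 1) * q$c2
    expect_equal(evaluate_surface(d1, d2, q), ode_steady_effect(d1, d2, q),
                 tolerance = 1e-5)
  }
})
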
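# Shared fixtures: reference parameter sets, designs, and the independent
# ODE steady-state oracle used to cross-check the algebraic surface.

# Reference two-drug surface used throughout the fitting tests.
ref_params <- function() {
  musyc_params(e0 = 1, e1 = 0.3, e2 = 0.5, e3 = 0.1,
               c1 = 1, c2 = 1, h1 = 1, h2 = 1,
               alpha12 = 3, alpha21 = 0.5)
}

ref_truth <- function() {
  c(E0 = 1, E1 = 0.3, E2 = 0.5, E3 = 0.1, C1 = 1, C2 = 1, h1 = 1, h2 = 1,
    log10_alpha12 = log10(3), log10_alpha21 = log10(0.5))
}

# 8 doses per drug (zero anchor + 7 log-spaced over 4 decades around the
# EC50s), the standard checkerboard of the recovery experiments.
ref_design <- function(n = 7, dmin = 0.01, dmax = 100) {
  sampling_design("grid",
                  doses1 = dose_grid(dmin, dmax, n),
                  doses2 = dose_grid(dmin, dmax, n))
}

# Random valid parameter set for property loops (call under a fixed seed).
rand_params <- function(h_range = c(0.5, 3), log_alpha_range = c(-2, 2),
                        gamma_range = c(0.5, 2)) {
  musyc_params(
    e0 = 1,
    e1 = runif(1, 0, 0.8), e2 = runif(1, 0, 0.8), e3 = runif(1, 0, 0.6),
    c1 = 10^runif(1, -1, 1), c2 = 10^runif(1, -1, 1),
    h1 = runif(1, h_range[1], h_range[2]),
    h2 = runif(1, h_range[1], h_range[2]),
    alpha12 = 10^runif(1, log_alpha_range[1], log_alpha_range[2]),
    alpha21 = 10^runif(1, log_alpha_range[1], log_alpha_range[2]),
    gamma12 = runif(1, gamma_range[1], gamma_range[2]),
    gamma21 = runif(1, gamma_range[1], gamma_range[2])
  )
}

# Independent oracle: integrate the four-state mass-action ODE system to its
# long-time limit and read off the effect. Deliberately shares no code with
# the package's matrix/cofactor solve.
ode_steady_effect <- function(d1, d2, p, t_end = 2000) {
  t1 <- p$r1 * d1^p$h1
  t2 <- p$r2 * d2^p$h2
  rm1 <- p$r1 * p$c1^p$h1
  rm2 <- p$r2 * p$c2^p$h2
  g12 <- p$r2^p$gamma12 * (p$alpha12 * d2)^(p$gamma12 * p$h2)
  g21 <- p$r1^p$gamma21 * (p$alpha21 * d1)^(p$gamma21 * p$h1)
  rm1g <- rm1^p$gamma21
  rm2g <- rm2^p$gamma12
  deriv <- function(t, y, parms) {
    U <- y[1]; A1 <- y[2]; A2 <- y[3]; A12 <- y[4]
    list(c(
      -U * (t1 + t2) + A1 * rm1 + A2 * rm2,
      -A1 * (rm1 + g12) + U * t1 + A12 * rm2g,
      -A2 * (g21 + rm2) + U * t2 + A12 * rm1g,
      -A12 * (rm1g + rm2g) + A1 * g12 + A2 * g21
    ))
  }
  out <- deSolve::ode(y = c(1, 0, 0, 0), times = c(0, t_end), func = deriv,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12, maxsteps = 1e6)
  s <- out[nrow(out), 2:5]
  sum(s * c(p$e0, p$e1, p$e2, p$e3))
}
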
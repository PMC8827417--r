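test_that("mean response, fraction active and mu satisfy their identities", {
  traj <- make_traj(matrix(c(0.2, 0.6, -1, -2), 4, 10))
  expect_equal(mean_response(traj), 0.2)
  expect_equal(fraction_active(traj), 0.5)
  expect_equal(active_mean(traj), 0.4)
  expect_equal(fraction_active(traj) * active_mean(traj),
               mean_response(traj))
  silent <- make_traj(matrix(-1, 3, 5))
  expect_equal(mean_response(silent), 0)
  expect_equal(fraction_active(silent), 0)
  expect_equal(active_mean(silent), 0)
  # Heaviside rates: mean response equals the fraction active exactly
  run <- std_highvar_run()
  expect_equal(mean_response(run$traj), fraction_active(run$traj),
               tolerance = 1e-14)
  expect_equal(fraction_active(run$traj) * active_mean(run$traj),
               mean_response(run$traj), tolerance = 1e-15)
})

test_that("variance decomposition is exact and matches the pooled variance", {
  m <- matrix(c(1, 3), 2, 8)
  v <- variance_decomposition(m)
  expect_equal(unname(v["var_temporal"]), 0)
  expect_equal(unname(v["var_quenched"]), 1)
  tr <- sin(seq(0, 20, length.out = 64)); tr <- tr - mean(tr)
  shared <- matrix(tr, 5, 64, byrow = TRUE)
  v2 <- variance_decomposition(shared)
  expect_equal(unname(v2["var_quenched"]), 0, tolerance = 1e-14)
  expect_equal(unname(v2["var_temporal"]), mean(tr^2), tolerance = 1e-12)
  set.seed(1)
  r <- matrix(rnorm(600), 20, 30)
  v3 <- variance_decomposition(r)
  expect_equal(unname(v3["var_total"]),
               unname(v3["var_temporal"] + v3["var_quenched"]))
  expect_equal(unname(v3["var_total"]), mean(r^2) - mean(r)^2,
               tolerance = 1e-12)
  expect_error(variance_decomposition(matrix(1, 1, 5)))
})

test_that("autocorrelation matches analytic fixtures", {
  set.seed(2)
  w <- matrix(rnorm(200 * 2000), 200, 2000)
  ac <- autocorrelation(w, max_lag = 1, dt_sample = 0.1)
  expect_equal(ac$R[1], unname(variance_decomposition(w)["var_temporal"]),
               tolerance = 1e-12)
  expect_lt(max(abs(ac$R[-1])), 0.02)
  # phase-randomized sinusoids: R(tau) -> 0.5 cos(tau)
  dt <- 2 * pi / 64
  t_grid <- dt * seq_len(64 * 120)
  phases <- seq(0, 2 * pi, length.out = 41)[-41]
  s <- t(vapply(phases, function(p) sin(t_grid + p), numeric(length(t_grid))))
  ac2 <- autocorrelation(s, max_lag = 2 * pi, dt_sample = dt)
  expect_lt(max(abs(ac2$R - 0.5 * cos(ac2$lag))), 0.02)
  # OU fixture: normalized decay ~ exp(-tau / tau_c)
  x <- ou_matrix(300, 4000, dt = 0.1, tau_c = 2, seed = 3)
  ac3 <- autocorrelation(x, max_lag = 4, dt_sample = 0.1)
  expect_lt(max(abs(ac3$R / ac3$R[1] - exp(-ac3$lag / 2))), 0.1)
  expect_error(autocorrelation(x, max_lag = 300, dt_sample = 0.1))
})

test_that("correlation time and beta follow the normalized-area definition", {
  lag <- seq(0, 30, by = 0.01)
  R <- exp(-lag / 2)
  expect_equal(correlation_time(R, lag), 2, tolerance = 1e-3)
  expect_equal(decorrelation_rate(R, lag), 0.5, tolerance = 1e-3)
  # delta-like autocorrelation: area collapses to one trapezoid
  Rd <- c(1, rep(0, 10))
  lagd <- 0.1 * (0:10)
  expect_equal(correlation_time(Rd, lagd), 0.05, tolerance = 1e-12)
  expect_gt(decorrelation_rate(Rd, lagd), 10)
  # truncation at the first zero crossing
  Rz <- c(1, 0.5, -0.2, 0.4)
  lz <- 0:3
  expect_equal(correlation_time(Rz, lz), pracma::trapz(0:2, c(1, 0.5, -0.2)),
               tolerance = 1e-12)
  expect_error(correlation_time(c(0, 1), 0:1))
})

test_that("synchrony index separates identical, independent and async traces", {
  tr <- ou_matrix(1, 2000, seed = 4)
  identical_units <- matrix(tr, 10, 2000, byrow = TRUE)
  expect_equal(synchrony_index(identical_units), 1, tolerance = 1e-12)
  ind25 <- ou_matrix(25, 6000, seed = 5)
  ind100 <- ou_matrix(100, 6000, seed = 6)
  s25 <- synchrony_index(ind25); s100 <- synchrony_index(ind100)
  expect_lt(abs(s25 - 1 / 25) / (1 / 25), 1)
  expect_lt(abs(s100 - 1 / 100) / (1 / 100), 1)
  expect_lt(s100, s25)
  expect_error(synchrony_index(matrix(1, 3, 4)))
})

test_that("on-time fractions and psi behave on binary and constant rates", {
  x <- matrix(rep(c(1, -1), 5), 1, 10)
  traj <- make_traj(x, nl = nonlinearity("heaviside"))
  expect_equal(unname(on_time_fraction(traj)), 0.5)
  expect_equal(psi_ratio(traj), 1)  # phi^2 = phi for binary rates
  const <- make_traj(matrix(0.3, 4, 6))
  expect_equal(psi_ratio(const), 0.3, tolerance = 1e-12)
  expect_error(psi_ratio(make_traj(matrix(-1, 2, 4))))
})

test_that("balance index is 1 for uncoupled units and errors for I0 = 0", {
  W <- matrix(0, 4, 4)
  cfg <- sim_config(I0 = 1.5, dt = 0.02, T = 40, burn_in = 30, seed = 1)
  traj <- simulate_network(W, nonlinearity("rect_tanh"), cfg)
  expect_equal(balance_index(traj), 1, tolerance = 1e-4)
  expect_error(balance_index(traj, I0 = 0))
})

test_that("gaussianity report flags non-normal samples", {
  set.seed(7)
  g <- gaussianity_report(rnorm(2e4))
  expect_lt(abs(g$skewness), 0.1)
  expect_lt(abs(g$excess_kurtosis), 0.2)
  expect_equal(g$frac_above, 0.5, tolerance = 0.02)
  e <- gaussianity_report(rexp(2e4))
  expect_gt(e$skewness, 1)
  expect_lt(e$p_value, 1e-4)
})

test_that("summary_stats returns the fixed column layout with identities", {
  run <- std_highvar_run()
  st <- summary_stats(run$traj)
  expect_named(st, c("K", "N", "family", "nu", "J0", "g", "I0", "phi_kind",
                     "lambda", "seed", "phi_bar", "f", "mu", "x_bar",
                     "var_t_x", "var_q_x", "var_t_eta", "var_q_eta",
                     "tau_eta", "beta", "chi", "psi", "sync"))
  expect_equal(st$phi_bar, st$f * st$mu)
  expect_equal(st$K, 800L)
  expect_equal(st$phi_kind, "heaviside")
  # low-pass filtering can only shrink the temporal variance
  expect_gt(st$var_t_eta, st$var_t_x)
  # quenched variance passes through the filter unchanged
  expect_equal(st$var_q_eta, st$var_q_x, tolerance = 0.15)
})
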
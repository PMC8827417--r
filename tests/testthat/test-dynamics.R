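test_that("nonlinearities evaluate their defining cases", {
  cases <- list(
    list(nonlinearity("heaviside"), c(-1, 0, 0.3, 2), c(0, 0, 1, 1)),
    list(nonlinearity("rect_tanh"), c(-1, 0, 1), c(0, 0, tanh(1))),
    list(nonlinearity("rect_power", 1), c(-2, 0.5, 3), c(0, 0.5, 3)),
    list(nonlinearity("rect_power", 2), c(-1, 2), c(0, 4)),
    list(nonlinearity("rect_power", 0), c(-1, 0, 0.2), c(0, 0, 1)),
    list(nonlinearity("linear"), c(-2, 3), c(-2, 3)))
  for (cs in cases)
    expect_equal(apply_nonlinearity(cs[[2]], cs[[1]]), cs[[3]])
  m <- matrix(c(-1, 1, 2, -3), 2)
  expect_equal(dim(apply_nonlinearity(m, nonlinearity("rect_tanh"))), c(2L, 2L))
  expect_error(nonlinearity("rect_power", -1))
})

test_that("decoupled units relax to the bias current", {
  W <- matrix(0, 5, 5)
  cfg <- sim_config(I0 = 1.3, dt = 0.02, T = 30, burn_in = 20, seed = 1)
  traj <- simulate_network(W, nonlinearity("rect_tanh"), cfg)
  expect_equal(unname(traj$x[, ncol(traj$x)]), rep(1.3, 5), tolerance = 1e-4)
  expect_equal(unname(traj$phi[, ncol(traj$phi)]), rep(tanh(1.3), 5),
               tolerance = 1e-4)
})

test_that("single-unit network converges to the scalar fixed point", {
  # oracle: root of x = I0 - J * tanh(x) by bisection
  root <- uniroot(function(x) x - (1 - 0.5 * tanh(x)), c(0, 1),
                  tol = 1e-12)$root
  W <- matrix(0.5, 1, 1)
  cfg <- sim_config(I0 = 1, dt = 0.02, T = 60, burn_in = 40, seed = 1)
  traj <- simulate_network(W, nonlinearity("rect_tanh"), cfg)
  expect_equal(traj$x[1, ncol(traj$x)], root, tolerance = 1e-6)
})

test_that("linear identity dynamics reproduce exponential relaxation", {
  W <- matrix(0, 3, 3)
  dt <- 0.02
  cfg <- sim_config(I0 = 2, dt = dt, T = 5, burn_in = 0, record_stride = 1,
                    seed = 1)
  x0 <- c(-1, 0, 3)
  traj <- simulate_network(W, nonlinearity("linear"), cfg, x0 = x0)
  expected <- outer(x0 - 2, exp(-traj$times)) + 2
  expect_lt(max(abs(traj$x - expected)), 5 * dt)
})

test_that("recorded eta is consistent with the currents via the update rule", {
  spec <- weight_spec("gamma", J0 = 2, g = 2, nu = 0.5, K = 100)
  W <- sample_weights(spec, seed = 2)
  dt <- 0.05
  cfg <- sim_config(I0 = 1, dt = dt, T = 15, burn_in = 5, record_stride = 1,
                    seed = 2, record_eta = TRUE)
  traj <- simulate_network(W, nonlinearity("rect_tanh"), cfg)
  # with stride 1, the Euler step gives exactly
  # x_k = x_{k-1} + dt * (I0 - x_{k-1} - eta_k)
  k <- 2:ncol(traj$x)
  eta_fd <- 1 - traj$x[, k - 1] - (traj$x[, k] - traj$x[, k - 1]) / dt
  expect_lt(max(abs(eta_fd - traj$eta[, k])), 1e-10)
})

test_that("attractor statistics are robust to seed and step size", {
  nl <- nonlinearity("rect_tanh")
  run <- function(seed, dt) {
    spec <- weight_spec("gamma", J0 = 2, g = 2, nu = 0.5, K = 400)
    W <- sample_weights(spec, seed = seed)
    traj <- simulate_network(W, nl, sim_config(I0 = 1, dt = dt, T = 250,
                                               burn_in = 100, seed = seed))
    c(phi_bar = mean_response(traj), f = fraction_active(traj),
      probe = traj$x[1, ncol(traj$x)])
  }
  a <- run(1, 0.05); a_half <- run(1, 0.025); b <- run(2, 0.05)
  # halving dt barely moves the averages
  expect_lt(abs(a["phi_bar"] - a_half["phi_bar"]) / a["phi_bar"], 0.1)
  expect_lt(abs(a["f"] - a_half["f"]) / a["f"], 0.1)
  # another realization changes microscopic state but not population stats
  expect_false(isTRUE(all.equal(a["probe"], b["probe"], tolerance = 1e-4)))
  expect_lt(abs(a["phi_bar"] - b["phi_bar"]) / a["phi_bar"], 0.25)
})

test_that("E-I network with zero coupling relaxes to the population biases", {
  W0 <- build_ei_matrix(J = c(EE = 0, EI = 0, IE = 0, II = 0), g = 1,
                        NE = 10, NI = 10, K = 3, seed = 1)
  cfg <- sim_config(dt = 0.02, T = 30, burn_in = 20, seed = 1)
  traj <- simulate_ei(W0, nonlinearity("rect_tanh"), IE = 2, II = 1, cfg)
  last <- traj$x[, ncol(traj$x)]
  expect_equal(unname(last[1:10]), rep(2, 10), tolerance = 1e-4)
  expect_equal(unname(last[11:20]), rep(1, 10), tolerance = 1e-4)
  expect_equal(levels(traj$labels), c("E", "I"))
})

test_that("divergent supralinear dynamics abort with a diagnostic", {
  # net self-excitation with a quadratic rate blows up in finite time
  W <- matrix(-10, 2, 2)  # negative inhibitory weight = excitation
  cfg <- sim_config(I0 = 1, dt = 0.05, T = 50, burn_in = 10, seed = 1)
  expect_error(
    simulate_network(W, nonlinearity("rect_power", 2), cfg,
                     x0 = c(1, 1)),
    "diverged")
})

test_that("population subsetting preserves structure", {
  run <- std_highvar_run()
  sub <- traj_subset(run$traj, 1:10)
  expect_equal(nrow(sub$x), 10)
  expect_equal(nrow(sub$eta), 10)
  expect_equal(sub$phi, apply_nonlinearity(sub$x, sub$nl))
})
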
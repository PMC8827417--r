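# Build an sb_trajectory directly from a current matrix, for statistics
# fixtures. The default rectified-linear nonlinearity makes phi equal to x
# wherever x > 0, so constant-rate fixtures are easy to write down.
make_traj <- function(x, nl = nonlinearity("rect_power", lambda = 1),
                      dt_samp = 0.1, eta = NULL, I0 = 1) {
  stopifnot(is.matrix(x))
  stride <- max(1L, round(dt_samp / 0.05))
  cfg <- sim_config(I0 = I0, dt = dt_samp / stride, T = dt_samp * ncol(x) + 1,
                    burn_in = 0, record_stride = stride, seed = 1L)
  structure(list(x = x, phi = apply_nonlinearity(x, nl), eta = eta,
                 times = dt_samp * seq_len(ncol(x)), nl = nl, cfg = cfg,
                 labels = NULL, meta = list()),
            class = "sb_trajectory")
}

# Independent Ornstein-Uhlenbeck traces: n units x nt samples, correlation
# time tau_c, unit stationary variance.
ou_matrix <- function(n, nt, dt = 0.1, tau_c = 2, seed = 1) {
  set.seed(seed)
  a <- exp(-dt / tau_c)
  x <- matrix(0, n, nt)
  x[, 1] <- rnorm(n)
  for (k in 2:nt)
    x[, k] <- a * x[, k - 1] + sqrt(1 - a^2) * rnorm(n)
  x
}

# One standard high-variance gamma network run, memoized across test files.
fixture_env <- new.env(parent = emptyenv())
std_highvar_run <- function() {
  if (is.null(fixture_env$highvar)) {
    spec <- weight_spec("gamma", J0 = 2, g = 2, nu = 0.5, K = 800)
    W <- sample_weights(spec, seed = 11)
    cfg <- sim_config(I0 = 1, dt = 0.05, T = 300, burn_in = 100, seed = 11,
                      record_eta = TRUE)
    traj <- simulate_network(W, nonlinearity("heaviside"), cfg)
    fixture_env$highvar <- list(spec = spec, traj = traj)
  }
  fixture_env$highvar
}
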
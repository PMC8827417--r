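#' Rate nonlinearity (F-I function)
#'
#' The static map from total current to firing rate. All kinds are rectified:
#' `phi(x) = 0` for `x <= 0` (a unit exactly at threshold is inactive).
#' `"heaviside"` gives binary rates, `"rect_tanh"` `tanh(x)` above threshold,
#' `"rect_power"` `x^lambda` above threshold (`lambda = 1` rectified linear,
#' `lambda = 2` rectified quadratic, `lambda = 0` reduces to the Heaviside).
#' `"linear"` is the unrectified identity on the whole line, kept for
#' integrator diagnostics only.
#'
#' @param kind one of `"rect_tanh"`, `"heaviside"`, `"rect_power"`,
#'   `"linear"`.
#' @param lambda exponent for `"rect_power"`, `>= 0`.
#' @return an object of class `nonlinearity`.
#' @export
nonlinearity <- function(kind = c("rect_tanh", "heaviside", "rect_power", "linear"),
                         lambda = 1) {
  kind <- match.arg(kind)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0)
    stop("`lambda` must be a single number >= 0")
  structure(list(kind = kind, lambda = lambda,
                 code = c(heaviside = 0L, rect_tanh = 1L,
                          rect_power = 2L, linear = 3L)[[kind]]),
            class = "nonlinearity")
}

#' Apply a nonlinearity to currents
#'
#' @param x numeric vector or matrix of currents.
#' @param nl a [nonlinearity()].
#' @return rates `phi(x)`, same shape as `x`.
#' @examples
#' apply_nonlinearity(c(-1, 0, 1), nonlinearity("rect_tanh"))
#' @export
apply_nonlinearity <- function(x, nl) {
  stopifnot(inherits(nl, "nonlinearity"))
  if (nl$kind == "linear") return(x)
  out <- x
  out[] <- 0
  pos <- which(x > 0)
  out[pos] <- switch(nl$kind,
    heaviside  = 1,
    rect_tanh  = tanh(x[pos]),
    rect_power = if (nl$lambda == 0) 1 else x[pos]^nl$lambda)
  out
}

#' Simulation configuration
#'
#' Settings for the forward-Euler integration of the rate equations. Time is
#' measured in units of the intrinsic time constant `tau_x = 1`. `T` is the
#' total simulated duration including the discarded `burn_in`; the recorded
#' window has length `T - burn_in`.
#'
#' @param I0 bias current, identical for all units (order 1).
#' @param dt Euler step, `0 < dt <= 0.05`; default 0.02.
#' @param T total duration, `> burn_in`.
#' @param burn_in discarded initial duration; default `100` (the chaotic
#'   attractor's statistics are reached well within 100 `tau_x`).
#' @param record_stride steps between stored samples; default gives at least
#'   10 samples per `tau_x` so autocorrelations are resolved below `tau_x`.
#' @param seed RNG seed for the initial condition.
#' @param record_eta logical; also record the recurrent synaptic input.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(I0 = 1, dt = 0.02, T = 1000, burn_in = 100,
                       record_stride = NULL, seed = 1L, record_eta = FALSE) {
  stopifnot(is.numeric(I0), length(I0) == 1L, is.finite(I0),
            dt > 0, dt <= 0.05, burn_in >= 0, T > burn_in)
  if (is.null(record_stride)) record_stride <- max(1L, floor(0.1 / dt))
  stopifnot(record_stride >= 1)
  structure(list(I0 = I0, tau_x = 1, dt = dt, T = T, burn_in = burn_in,
                 record_stride = as.integer(record_stride),
                 seed = as.integer(seed), record_eta = isTRUE(record_eta)),
            class = "sim_config")
}

coupling_values <- function(W) {
  if (inherits(W, "weight_matrix")) W$values
  else if (is.matrix(W)) W
  else stop("`W` must be a weight_matrix or a numeric matrix")
}

make_trajectory <- function(core, nl, cfg, labels = NULL, meta = list(),
                            eta_sign = 1) {
  phi <- apply_nonlinearity(core$x, nl)
  traj <- list(x = core$x, phi = phi, times = as.numeric(core$times),
               nl = nl, cfg = cfg, labels = labels, meta = meta)
  if (!is.null(core$drive)) traj$eta <- eta_sign * core$drive
  structure(traj, class = "sb_trajectory")
}

#' Simulate a single-population inhibitory network
#'
#' Integrates `tau_x dx_i/dt = -x_i - sum_j J_ij phi(x_j) + I0` by forward
#' Euler with nonnegative couplings `J` acting inhibitorily. Burn-in is
#' discarded and the state recorded every `record_stride` steps. When
#' `cfg$record_eta` is set, the recurrent synaptic input
#' `eta_i = sum_j J_ij phi(x_j)` is recorded alongside.
#'
#' @param W a `weight_matrix` from [sample_weights()] (or a plain nonnegative
#'   matrix).
#' @param nl a [nonlinearity()].
#' @param cfg a [sim_config()].
#' @param x0 optional initial currents; by default i.i.d. `N(0, 0.1^2)` drawn
#'   under `cfg$seed` (attractor statistics are initial-condition
#'   independent).
#' @return an `sb_trajectory`: list with `x`, `phi` (units x times matrices),
#'   optionally `eta`, plus `times`, `nl`, `cfg`, and sampling metadata.
#'   Divergent dynamics (possible for `rect_power` with `lambda > 1`) abort
#'   with an error naming the failing step.
#' @examples
#' W <- sample_weights(weight_spec("gamma", J0 = 2, g = 2, K = 200), seed = 1)
#' traj <- simulate_network(W, nonlinearity("rect_tanh"),
#'                          sim_config(T = 60, burn_in = 20, seed = 1))
#' mean_response(traj)
#' @export
simulate_network <- function(W, nl, cfg, x0 = NULL) {
  vals <- coupling_values(W)
  N <- nrow(vals)
  signed <- inherits(W, "weight_matrix") && isTRUE(W$signed)
  if (signed)
    stop("signed E-I matrices are integrated with simulate_ei()")
  if (is.null(x0)) {
    set.seed(cfg$seed)
    x0 <- 0.1 * rnorm(N)
  }
  steps <- steps_of(cfg)
  core <- .sim_core(-vals, nl$code, nl$lambda, rep(cfg$I0, N), cfg$dt,
                    steps$burn, steps$run, cfg$record_stride, x0,
                    cfg$record_eta)
  meta <- if (inherits(W, "weight_matrix"))
    c(W$spec, list(seed = W$seed)) else list(N = N)
  make_trajectory(core, nl, cfg, meta = meta, eta_sign = -1)
}

#' Simulate a two-population E-I network
#'
#' Integrates `dx_i/dt = -x_i + [E input] - [I input] + I_pop` for a signed
#' block matrix from [build_ei_matrix()]; the excitatory/inhibitory signs are
#' carried by the matrix columns. Population labels are preserved in the
#' output.
#'
#' @param W signed `weight_matrix` from [build_ei_matrix()].
#' @param nl a [nonlinearity()].
#' @param IE,II bias currents of the excitatory and inhibitory populations.
#' @param cfg a [sim_config()] (`cfg$I0` is ignored in favour of `IE`/`II`).
#' @param x0 optional initial currents.
#' @return an `sb_trajectory` with a `labels` factor (`"E"`/`"I"` per unit);
#'   `eta`, when recorded, is the signed net recurrent input.
#' @export
simulate_ei <- function(W, nl, IE = 2, II = 1, cfg, x0 = NULL) {
  stopifnot(inherits(W, "weight_matrix"), isTRUE(W$signed))
  vals <- W$values
  N <- nrow(vals)
  bias <- c(rep(IE, W$NE), rep(II, W$NI))
  if (is.null(x0)) {
    set.seed(cfg$seed)
    x0 <- 0.1 * rnorm(N)
  }
  steps <- steps_of(cfg)
  core <- .sim_core(vals, nl$code, nl$lambda, bias, cfg$dt,
                    steps$burn, steps$run, cfg$record_stride, x0,
                    cfg$record_eta)
  meta <- c(W$spec, list(J_blocks = W$J_blocks, IE = IE, II = II,
                         seed = W$seed, NE = W$NE, NI = W$NI))
  make_trajectory(core, nl, cfg, labels = W$labels, meta = meta)
}

steps_of <- function(cfg) {
  list(burn = as.integer(round(cfg$burn_in / cfg$dt)),
       run  = as.integer(round((cfg$T - cfg$burn_in) / cfg$dt)))
}

#' Restrict a trajectory to a subset of units
#'
#' @param traj an `sb_trajectory`.
#' @param units integer indices, logical mask, or a population label
#'   (`"E"`/`"I"`) for labelled E-I trajectories.
#' @return an `sb_trajectory` over the selected units.
#' @export
traj_subset <- function(traj, units) {
  stopifnot(inherits(traj, "sb_trajectory"))
  if (is.character(units)) {
    stopifnot(!is.null(traj$labels))
    units <- traj$labels %in% units
  }
  out <- traj
  out$x <- traj$x[units, , drop = FALSE]
  out$phi <- traj$phi[units, , drop = FALSE]
  if (!is.null(traj$eta)) out$eta <- traj$eta[units, , drop = FALSE]
  if (!is.null(traj$labels)) out$labels <- droplevels(traj$labels[units])
  out
}

#' @export
print.sb_trajectory <- function(x, ...) {
  cat(sprintf("<sb_trajectory> %d units x %d samples (dt = %g, stride = %d), phi = %s\n",
              nrow(x$x), ncol(x$x), x$cfg$dt, x$cfg$record_stride, x$nl$kind))
  if (!is.null(x$labels))
    cat(sprintf("  populations: %s\n",
                paste(sprintf("%s = %d", levels(x$labels), table(x$labels)),
                      collapse = ", ")))
  invisible(x)
}
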
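#' Mean network response
#'
#' Average rate over all units and recorded times,
#' `phi_bar = mean_i mean_t phi(x_i(t))`. In the sparse-balance regime this
#' scales as `1/sqrt(K)`.
#'
#' @param traj an `sb_trajectory` (burn-in already discarded by the
#'   integrator).
#' @return scalar `phi_bar`.
#' @export
mean_response <- function(traj) {
  stopifnot(inherits(traj, "sb_trajectory"), length(traj$phi) > 0)
  mean(traj$phi)
}

#' Fraction of active units
#'
#' Time average of the per-timestep fraction of units with `phi > 0`
#' (strictly above threshold). Its inverse is the sparsity.
#'
#' @param traj an `sb_trajectory`.
#' @return scalar `f` in `[0, 1]`.
#' @export
fraction_active <- function(traj) {
  stopifnot(inherits(traj, "sb_trajectory"), length(traj$phi) > 0)
  mean(traj$phi > 0)
}

#' Mean rate of the active units
#'
#' `mu = phi_bar / f`, so that `phi_bar = f * mu` exactly; defined as 0 when
#' no unit is ever active.
#'
#' @param traj an `sb_trajectory`.
#' @return scalar `mu`.
#' @export
active_mean <- function(traj) {
  f <- fraction_active(traj)
  if (f == 0) 0 else mean_response(traj) / f
}

#' Temporal/quenched variance decomposition
#'
#' Splits the pooled variance of a units-by-times signal into the temporal
#' variance (population average of per-unit variances around their own time
#' means) and the quenched variance (variance across units of the per-unit
#' time means). Population (1/n) normalization is used throughout so the
#' identity `var_total = var_temporal + var_quenched` is exact, with
#' `var_total` equal to the variance over the pooled unit-by-time sample.
#'
#' @param signal numeric matrix, units in rows, times in columns (at least 2
#'   of each).
#' @return named vector `c(var_total, var_temporal, var_quenched)`.
#' @export
variance_decomposition <- function(signal) {
  stopifnot(is.matrix(signal), nrow(signal) >= 2, ncol(signal) >= 2)
  m1 <- rowMeans(signal)
  m2 <- rowMeans(signal^2)
  var_t <- mean(m2 - m1^2)
  var_q <- mean(m1^2) - mean(m1)^2
  c(var_total = var_t + var_q, var_temporal = var_t, var_quenched = var_q)
}

#' Population-averaged autocorrelation function
#'
#' Per-unit autocovariance of the signal around its own time mean, averaged
#' over units: `R(tau) = mean_i < (s_i(t) - <s_i>)(s_i(t + tau) - <s_i>) >`.
#' The biased (1/n) estimator is used so `R(0)` equals the temporal variance
#' of the decomposition exactly. Computed via FFT across units.
#'
#' @param signal units-by-times matrix, or an `sb_trajectory` (then `which`
#'   selects the signal).
#' @param max_lag largest lag, in time units; must not exceed half the
#'   recorded window.
#' @param dt_sample sampling interval of the columns; taken from the
#'   trajectory when one is supplied.
#' @param which for trajectories: `"eta"` (default when recorded) or `"x"`.
#' @return list with `lag` (time lags, starting at 0) and `R`.
#' @export
autocorrelation <- function(signal, max_lag, dt_sample = NULL, which = NULL) {
  if (inherits(signal, "sb_trajectory")) {
    traj <- signal
    if (is.null(which)) which <- if (!is.null(traj$eta)) "eta" else "x"
    signal <- switch(which, eta = traj$eta, x = traj$x,
                     stop("`which` must be 'eta' or 'x'"))
    if (is.null(signal)) stop("trajectory has no recorded eta")
    dt_sample <- traj$cfg$dt * traj$cfg$record_stride
  }
  stopifnot(is.matrix(signal), !is.null(dt_sample), dt_sample > 0)
  nt <- ncol(signal)
  n_lag <- floor(max_lag / dt_sample)
  if (n_lag > nt / 2) stop("`max_lag` exceeds half the recorded window")
  npad <- 2^ceiling(log2(2 * nt))
  n_units <- nrow(signal)
  acc <- numeric(n_lag + 1L)
  # blocks of units keep the FFT workspace bounded for large networks
  block <- max(1L, min(n_units, floor(2^25 / npad)))
  for (i0 in seq(1L, n_units, by = block)) {
    idx <- i0:min(i0 + block - 1L, n_units)
    Xp <- matrix(0, npad, length(idx))
    Xp[seq_len(nt), ] <- t(signal[idx, , drop = FALSE] -
                             rowMeans(signal[idx, , drop = FALSE]))
    F <- stats::mvfft(Xp)
    ac <- Re(stats::mvfft(Mod(F)^2, inverse = TRUE)) / npad
    acc <- acc + rowSums(ac[seq_len(n_lag + 1L), , drop = FALSE])
  }
  list(lag = dt_sample * (0:n_lag), R = acc / (n_units * nt))
}

#' Correlation time of the recurrent input
#'
#' Normalized area under the autocorrelation function,
#' `tau = (1 / R(0)) * integral R(tau) dtau`, trapezoidally integrated from
#' lag 0 to the first lag at which `R` crosses zero (chaotic-network
#' autocorrelations decay into a noise floor, so the infinite upper limit is
#' truncated there), or to the largest available lag if `R` stays positive.
#'
#' @param R autocorrelation values on `lag` (as from [autocorrelation()]),
#'   or the list returned by [autocorrelation()].
#' @param lag lags, ignored when `R` is a list.
#' @return correlation time, in units of `tau_x`.
#' @export
correlation_time <- function(R, lag = NULL) {
  if (is.list(R)) { lag <- R$lag; R <- R$R }
  stopifnot(length(R) == length(lag), length(R) >= 2)
  if (R[1] <= 0) stop("R(0) must be positive")
  cross <- which(R <= 0)
  keep <- if (length(cross)) seq_len(cross[1]) else seq_along(R)
  if (length(keep) < 2) keep <- 1:2
  pracma::trapz(lag[keep], R[keep]) / R[1]
}

#' Decorrelation rate
#'
#' `beta = tau_x / tau_eta` with `tau_x = 1`; grows like `log K` in the
#' sparse-balance regime while staying flat in the low-variance network.
#'
#' @inheritParams correlation_time
#' @return scalar `beta`.
#' @export
decorrelation_rate <- function(R, lag = NULL) {
  1 / correlation_time(R, lag)
}

#' Synchrony index
#'
#' Chi-squared population-variance measure of synchrony: the temporal
#' variance of the population-averaged signal divided by the population
#' average of the per-unit temporal variances. Identical traces give 1; `N`
#' independent units give ~`1/N`; an asynchronous chaotic sparse-balance
#' network is orders of magnitude below 1. Computed on the rates by default
#' (weak negative current correlations in inhibitory networks make the
#' rate-based index the one that reaches the ~1e-4 asynchronous floor);
#' pass `which = "x"` for the current-based variant.
#'
#' @param x units-by-times signal matrix, or an `sb_trajectory`.
#' @param which for trajectories: `"phi"` (default) or `"x"`.
#' @return dimensionless synchrony index.
#' @export
synchrony_index <- function(x, which = c("phi", "x")) {
  if (inherits(x, "sb_trajectory")) {
    which <- match.arg(which)
    x <- if (which == "phi") x$phi else x$x
  }
  stopifnot(is.matrix(x), nrow(x) >= 2)
  popmean <- colMeans(x)
  num <- mean(popmean^2) - mean(popmean)^2
  den <- mean(rowMeans(x^2) - rowMeans(x)^2)
  if (den <= 0) stop("zero temporal variance: synchrony index undefined")
  num / den
}

#' Per-unit ON-time fractions
#'
#' Fraction of recorded time each unit spends above threshold
#' (`phi > 0`). In the sparse-balance regime the distribution across units is
#' wide and right-skewed, with most units active only occasionally.
#'
#' @param traj an `sb_trajectory`.
#' @return numeric vector of per-unit fractions in `[0, 1]`.
#' @export
on_time_fraction <- function(traj) {
  stopifnot(inherits(traj, "sb_trajectory"))
  rowMeans(traj$phi > 0)
}

#' Rate moment ratio psi
#'
#' Second-to-first moment ratio of the rates,
#' `psi = mean(phi^2) / mean(phi)` (pooled over units and time). For binary
#' (Heaviside) rates `psi = 1`; for constant rate `c`, `psi = c`.
#'
#' @param traj an `sb_trajectory`.
#' @return scalar `psi`.
#' @export
psi_ratio <- function(traj) {
  pb <- mean_response(traj)
  if (pb == 0) stop("mean response is zero: psi undefined")
  mean(traj$phi^2) / pb
}

#' Balance index
#'
#' `chi = x_bar / I0`: the ratio of the mean total current to the bias
#' current. Order 1 in the sparse-balance regime, shrinking toward 0 with
#' `K` in conventionally balanced / low-variance networks.
#'
#' @param traj an `sb_trajectory`.
#' @param I0 bias current; defaults to the one in the trajectory's config.
#' @return scalar `chi`.
#' @export
balance_index <- function(traj, I0 = traj$cfg$I0) {
  stopifnot(inherits(traj, "sb_trajectory"))
  if (I0 == 0) stop("balance index undefined for I0 = 0")
  mean(traj$x) / I0
}

#' Shape diagnostics of the current distribution
#'
#' Moment-based shape statistics of the pooled current samples plus an
#' Anderson-Darling normality statistic and the supra-threshold mass. The
#' test is run on an evenly thinned subsample of at most `max_n` values so
#' results are comparable across runs of different length.
#'
#' @param x numeric vector/matrix of currents, or an `sb_trajectory`.
#' @param max_n subsample cap for the normality test.
#' @return list with `skewness`, `excess_kurtosis` (moment estimators),
#'   `ad_stat`, `p_value` (Anderson-Darling), `frac_above` (mass with
#'   `x > 0`), `mean`, and `n_used`.
#' @export
gaussianity_report <- function(x, max_n = 5000) {
  if (inherits(x, "sb_trajectory")) x <- x$x
  x <- as.numeric(x)
  stopifnot(length(x) >= 8)
  idx <- if (length(x) > max_n)
    unique(round(seq(1, length(x), length.out = max_n))) else seq_along(x)
  ad <- nortest::ad.test(x[idx])
  list(skewness = e1071::skewness(x, type = 1),
       excess_kurtosis = e1071::kurtosis(x, type = 1),
       ad_stat = unname(ad$statistic), p_value = ad$p.value,
       frac_above = mean(x > 0), mean = mean(x), n_used = length(idx))
}

#' All summary statistics of a trajectory
#'
#' One row collecting every scalar statistic used to characterize the
#' sparse-balance regime, in a fixed column order suitable for appending to
#' a sweep CSV. Autocorrelation-based quantities (`tau_eta`, `beta`) use the
#' recurrent input `eta` when it was recorded and the current `x` otherwise.
#'
#' @param traj an `sb_trajectory`.
#' @param max_lag largest autocorrelation lag (time units); default 10 or
#'   half the window, whichever is smaller.
#' @return one-row `data.frame` with columns `K, N, family, nu, J0, g, I0,
#'   phi_kind, lambda, seed, phi_bar, f, mu, x_bar, var_t_x, var_q_x,
#'   var_t_eta, var_q_eta, tau_eta, beta, chi, psi, sync`.
#' @export
summary_stats <- function(traj, max_lag = NULL) {
  stopifnot(inherits(traj, "sb_trajectory"))
  m <- traj$meta
  dt_samp <- traj$cfg$dt * traj$cfg$record_stride
  window <- dt_samp * ncol(traj$x)
  if (is.null(max_lag)) max_lag <- min(10, window / 2)
  ac <- autocorrelation(traj, max_lag = max_lag)
  vx <- variance_decomposition(traj$x)
  ve <- if (!is.null(traj$eta)) variance_decomposition(traj$eta)
        else c(var_temporal = NA_real_, var_quenched = NA_real_)
  tau_eta <- correlation_time(ac)
  data.frame(
    K = m$K %||% NA_integer_, N = nrow(traj$x),
    family = m$family %||% NA_character_, nu = m$nu %||% NA_real_,
    J0 = m$J0 %||% NA_real_, g = m$g %||% NA_real_, I0 = traj$cfg$I0,
    phi_kind = traj$nl$kind, lambda = traj$nl$lambda,
    seed = traj$cfg$seed,
    phi_bar = mean_response(traj), f = fraction_active(traj),
    mu = active_mean(traj), x_bar = mean(traj$x),
    var_t_x = unname(vx["var_temporal"]), var_q_x = unname(vx["var_quenched"]),
    var_t_eta = unname(ve["var_temporal"]),
    var_q_eta = unname(ve["var_quenched"]),
    tau_eta = tau_eta, beta = 1 / tau_eta,
    chi = if (traj$cfg$I0 != 0) balance_index(traj) else NA_real_,
    psi = if (mean(traj$phi) > 0) psi_ratio(traj) else NA_real_,
    sync = synchrony_index(traj),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
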
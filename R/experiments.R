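#' Scaling sweep over the in-degree K
#'
#' For each combination of `K` and seed: sample a weight matrix, integrate
#' the network, and collect [summary_stats()] plus, for gamma-family
#' high-variance networks, the closed-form predictions for the recurrent
#' input (`alpha`, `theta`, predicted mean current). Divergent simulations
#' (possible for supralinear rates) are flagged in the `diverged` column
#' rather than dropped.
#'
#' @param K_values in-degrees to sweep (>= 3 values spanning a decade for
#'   meaningful exponent fits).
#' @param seeds integer vector of seeds per K.
#' @param family,J0,g,nu weight-distribution settings (see [weight_spec()]).
#' @param nl a [nonlinearity()].
#' @param I0 bias current.
#' @param N network size; default `K` (dense).
#' @param dt,T,burn_in integrator settings (see [sim_config()]).
#' @param record_eta record the synaptic input (needed for `tau_eta`/`beta`
#'   of `eta`); default TRUE.
#' @param max_lag autocorrelation lag horizon.
#' @param quiet suppress per-run progress lines.
#' @return `data.frame`, one row per `K` x seed, in the fixed
#'   [summary_stats()] column order plus prediction and `diverged` columns.
#' @export
run_scaling_sweep <- function(K_values, seeds = 1:3,
                              family = "gamma", J0 = 2, g = 2, nu = 0.5,
                              nl = nonlinearity("rect_tanh"), I0 = 1,
                              N = NULL, dt = 0.02, T = 1000, burn_in = 100,
                              record_eta = TRUE, max_lag = 10, quiet = TRUE) {
  rows <- list()
  for (K in K_values) {
    Nk <- if (is.null(N)) K else N
    for (sd_i in seeds) {
      spec <- weight_spec(family, J0 = J0, g = g, nu = nu, K = K, N = Nk)
      W <- sample_weights(spec, seed = sd_i)
      cfg <- sim_config(I0 = I0, dt = dt, T = T, burn_in = burn_in,
                        seed = sd_i, record_eta = record_eta)
      row <- tryCatch({
        traj <- simulate_network(W, nl, cfg)
        st <- summary_stats(traj, max_lag = max_lag)
        st$diverged <- FALSE
        st
      }, error = function(e) {
        if (!grepl("diverged", conditionMessage(e))) stop(e)
        data.frame(K = K, N = Nk, family = family, nu = nu, J0 = J0, g = g,
                   I0 = I0, phi_kind = nl$kind, lambda = nl$lambda,
                   seed = sd_i, phi_bar = NA_real_, f = NA_real_,
                   mu = NA_real_, x_bar = NA_real_, var_t_x = NA_real_,
                   var_q_x = NA_real_, var_t_eta = NA_real_,
                   var_q_eta = NA_real_, tau_eta = NA_real_, beta = NA_real_,
                   chi = NA_real_, psi = NA_real_, sync = NA_real_,
                   diverged = TRUE, stringsAsFactors = FALSE)
      })
      if (family == "gamma" && !row$diverged && row$f > 0) {
        ep <- eta_distribution_params(row$f, spec)
        row$eta_alpha <- ep$alpha
        row$eta_theta <- ep$theta
        row$x_bar_pred <- balance_relation(row$f, J0, K, I0)
      } else {
        row$eta_alpha <- row$eta_theta <- row$x_bar_pred <- NA_real_
      }
      rows[[length(rows) + 1L]] <- row
      rm(W); gc(FALSE)  # large trajectories: release before the next run
      if (!quiet)
        message(sprintf("K = %d seed = %d: phi_bar = %.4g f = %.4g",
                        K, sd_i, row$phi_bar, row$f))
    }
  }
  do.call(rbind, rows)
}

#' Power-law exponent fit
#'
#' Ordinary least squares of `log(y)` on `log(K)`. The `exponent` is the
#' negative slope, so a decay `y ~ K^(-a)` yields `exponent = a`.
#'
#' @param K positive predictor values (in-degrees).
#' @param y positive response values.
#' @return object of class `power_law_fit`: list with `exponent`,
#'   `intercept` (on the log scale), `r_squared`, and `se` (standard error
#'   of the slope).
#' @examples
#' fit_power_law(c(100, 1000, 10000), c(100, 1000, 10000)^-0.5)
#' @export
fit_power_law <- function(K, y) {
  stopifnot(length(K) == length(y), length(K) >= 3)
  if (any(y <= 0)) stop("power-law fit requires positive y values")
  fit <- lm(log(y) ~ log(K))
  sm <- suppressWarnings(summary(fit))  # exact power laws trip lm's perfect-fit warning
  structure(list(exponent = -unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = sm$r.squared,
                 se = sm$coefficients[2, 2]),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> y ~ K^(-%.4f)  (se %.4f, R^2 %.4f)\n",
              x$exponent, x$se, x$r_squared))
  invisible(x)
}

#' Population response to the bias current
#'
#' Summary statistics versus the bias `I0` at fixed connectivity
#' realization(s): for each seed one weight matrix is sampled and simulated
#' across the whole `I0` grid. In the low-variance regime the mean response
#' is linear in `I0`; in the sparse-balance regime it inherits the
#' sub/supralinearity of the rate nonlinearity, while `f` is insensitive to
#' `I0` in both.
#'
#' @param I0_values bias-current grid.
#' @param K in-degree (fixed).
#' @param seeds connectivity seeds.
#' @inheritParams run_scaling_sweep
#' @return `data.frame` with one row per `I0` x seed: `I0`, `seed`,
#'   `phi_bar`, `f`, `mu`, `x_bar`.
#' @export
input_response_curve <- function(I0_values, K, seeds = 1L,
                                 family = "gamma", J0 = 2, g = 2, nu = 0.5,
                                 nl = nonlinearity("rect_tanh"), N = NULL,
                                 dt = 0.02, T = 500, burn_in = 100) {
  Nk <- if (is.null(N)) K else N
  rows <- list()
  for (sd_i in seeds) {
    spec <- weight_spec(family, J0 = J0, g = g, nu = nu, K = K, N = Nk)
    W <- sample_weights(spec, seed = sd_i)
    for (I0 in I0_values) {
      cfg <- sim_config(I0 = I0, dt = dt, T = T, burn_in = burn_in,
                        seed = sd_i)
      traj <- simulate_network(W, nl, cfg)
      rows[[length(rows) + 1L]] <- data.frame(
        I0 = I0, seed = sd_i, phi_bar = mean_response(traj),
        f = fraction_active(traj), mu = active_mean(traj),
        x_bar = mean(traj$x))
    }
  }
  do.call(rbind, rows)
}

#' Linearity diagnostics of a response curve
#'
#' R-squared of the straight-line fit of `y` on `I0` together with the
#' second differences of the seed-averaged curve; systematically negative
#' second differences indicate a sublinear population response.
#'
#' @param I0 bias values (need not be sorted; averaged over duplicates).
#' @param y response values (e.g. `phi_bar`).
#' @return list with `r_squared_linear` and `second_diffs`.
#' @export
linearity_diagnostics <- function(I0, y) {
  stopifnot(length(I0) == length(y), length(unique(I0)) >= 3)
  ym <- tapply(y, I0, mean)
  xs <- as.numeric(names(ym))
  o <- order(xs)
  xs <- xs[o]; ym <- as.numeric(ym)[o]
  fit <- lm(ym ~ xs)
  list(r_squared_linear = summary(fit)$r.squared,
       second_diffs = diff(diff(ym)) / diff(xs)[-1]^2)
}

#' Append summary rows to a sweep CSV
#'
#' Writes (or appends to) a statistics table with the fixed column order of
#' [run_scaling_sweep()], so repeated sweeps accumulate in one file with
#' enough metadata to re-run any row.
#'
#' @param rows `data.frame` of sweep rows.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
append_sweep_csv <- function(rows, path) {
  exists <- file.exists(path)
  suppressWarnings(
    write.table(rows, path, sep = ",", append = exists,
                col.names = !exists, row.names = FALSE))
  invisible(path)
}
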
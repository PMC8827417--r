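#' Dynamic mean-field parameters
#'
#' Parameter set for the dynamic mean-field theory (DMFT) of the
#' sparse-balance network with Gaussian-distributed weights (mean
#' `J0/sqrt(K)` entering the dynamics inhibitorily, variance `g^2/sqrt(K)`).
#' The theory replaces the network by a self-consistent single-unit process
#' `x = u + quenched + temporal` with Gaussian quenched (`z`) and temporal
#' (`xi`) components.
#'
#' @param J0,g coupling scales, `> 0`.
#' @param K in-degree, `>= 1`.
#' @param I0 bias current.
#' @param nl a [nonlinearity()] (`"rect_tanh"` or `"heaviside"` are the
#'   analytically sensible choices).
#' @param quad_order Gauss-Hermite node count for the Gaussian averages,
#'   `>= 8`; default 64.
#' @param tau_max integration horizon for the autocorrelation, in `tau_x`.
#' @return an object of class `dmft_params`.
#' @export
dmft_params <- function(J0 = 3, g = 2, K, I0 = 1,
                        nl = nonlinearity("rect_tanh"),
                        quad_order = 64, tau_max = 50) {
  stopifnot(J0 > 0, g > 0, K >= 1, inherits(nl, "nonlinearity"),
            quad_order >= 8, tau_max > 0)
  structure(list(J0 = J0, g = g, K = K, I0 = I0, nl = nl,
                 quad_order = as.integer(quad_order), tau_max = tau_max),
            class = "dmft_params")
}

# Gauss-Hermite rule transformed to the standard normal measure, memoized.
gh_cache <- new.env(parent = emptyenv())
gh_rule <- function(order) {
  key <- as.character(order)
  if (is.null(gh_cache[[key]])) {
    r <- pracma::gaussHermite(order)
    gh_cache[[key]] <- list(z = sqrt(2) * r$x, w = r$w / sqrt(pi))
  }
  gh_cache[[key]]
}

# Gauss-Legendre rule on [0, 1], memoized.
gl_rule <- function(order) {
  key <- paste0("gl", order)
  if (is.null(gh_cache[[key]])) {
    r <- pracma::gaussLegendre(order, 0, 1)
    gh_cache[[key]] <- list(x = r$x, w = r$w)
  }
  gh_cache[[key]]
}

# Smooth positive branch of the rectified nonlinearity (and its square).
phi_branch <- function(nl, squared = FALSE) {
  f <- switch(nl$kind,
    rect_tanh = tanh,
    rect_power = if (nl$lambda == 0) function(x) rep(1, length(x))
                 else function(x) x^nl$lambda,
    linear = identity,
    heaviside = function(x) rep(1, length(x)))
  if (squared) function(x) f(x)^2 else f
}

# int Dz f(a + b z) * 1[a + b z > 0], vectorized over a. The rectification
# kink at z = -a/b ruins spectral Gauss-Hermite convergence, so the integral
# is taken over the smooth positive branch only, with Gauss-Legendre nodes
# between the kink and the +8.5 sd tail cutoff.
kinked_gauss_mean <- function(a, b, f, order = 48) {
  if (b == 0) return(ifelse(a > 0, f(a), 0) * (a > 0))
  gl <- gl_rule(order)
  lo <- pmax(-a / b, -8.5)
  span <- pmax(8.5 - lo, 0)
  nodes <- lo + span %o% gl$x                # n_a x order
  vals <- f(a + b * nodes) * stats::dnorm(nodes)
  as.numeric(vals %*% gl$w) * span
}

# Inner temporal average int Dxi phi(u_eff + sd * xi), vectorized in u_eff.
# Closed form for the Heaviside; kink-split quadrature otherwise.
phi_inner_mean <- function(u_eff, sd, nl, order = 48) {
  if (sd == 0) return(as.numeric(apply_nonlinearity(u_eff, nl)))
  if (nl$kind == "heaviside") return(pnorm(u_eff / sd))
  if (nl$kind == "linear") return(u_eff)
  kinked_gauss_mean(u_eff, sd, phi_branch(nl), order = order)
}

#' Nested Gaussian average over quenched and temporal components
#'
#' Computes the population mean and mean-square of the time-averaged
#' response, `[<fn>]` and `[<fn>^2]`, over
#' `x = u + quenched_sd * z + temporal_sd * xi` with `z`, `xi` independent
#' standard normals, by Gauss-Hermite quadrature. When `fn` is a
#' [nonlinearity()] the Heaviside inner integral is replaced by its normal
#' CDF closed form.
#'
#' @param fn scalar function (vectorized) or a [nonlinearity()].
#' @param u deterministic offset.
#' @param quenched_sd,temporal_sd standard deviations, `>= 0`.
#' @param order quadrature order, `>= 8`.
#' @return list with `mean` (`[<fn>]`) and `meansq` (`[<fn>^2]`).
#' @export
double_gaussian_average <- function(fn, u, quenched_sd, temporal_sd,
                                    order = 64) {
  stopifnot(quenched_sd >= 0, temporal_sd >= 0)
  if (order < 8) stop("quadrature order below 8 refused")
  if (inherits(fn, "nonlinearity")) {
    if (quenched_sd == 0) {
      m <- phi_inner_mean(u, temporal_sd, fn, order)
      if (temporal_sd == 0) return(list(mean = m, meansq = m^2))
      m2 <- if (fn$kind == "heaviside") m
            else if (fn$kind == "linear") u^2 + temporal_sd^2
            else kinked_gauss_mean(u, temporal_sd, phi_branch(fn, TRUE), order)
      return(list(mean = m, meansq = m2))
    }
    if (temporal_sd == 0) {
      # the time average is phi itself: the z integral carries the kink
      m <- phi_inner_mean(u, quenched_sd, fn, order)
      m2 <- if (fn$kind == "heaviside") m
            else if (fn$kind == "linear") u^2 + quenched_sd^2
            else kinked_gauss_mean(u, quenched_sd, phi_branch(fn, TRUE), order)
      return(list(mean = m, meansq = m2))
    }
    # smooth (Gaussian-smoothed) inner mean, but with a sharp transition
    # around z* = -u / quenched_sd when the temporal sd is small: integrate
    # z on Gauss-Legendre panels split at the transition
    sp <- split_normal_rule(-u / quenched_sd, order)
    inner <- phi_inner_mean(u + quenched_sd * sp$z, temporal_sd, fn, order)
    return(list(mean = sum(sp$w * inner), meansq = sum(sp$w * inner^2)))
  }
  gh <- gh_rule(order)
  u_eff <- u + quenched_sd * gh$z
  inner <- if (temporal_sd == 0) fn(u_eff)
           else as.numeric(fn(outer(u_eff, temporal_sd * gh$z, "+")) %*% gh$w)
  list(mean = sum(gh$w * inner), meansq = sum(gh$w * inner^2))
}

# Quadrature rule for int Dz h(z) with h smooth except for a sharp (but
# continuous) transition near z = split: two Gauss-Legendre panels on
# [-8.5, split] and [split, 8.5], weighted by the normal density.
split_normal_rule <- function(split, order = 48) {
  gl <- gl_rule(order)
  s <- min(max(split, -8.5), 8.5)
  z <- c(-8.5 + (s + 8.5) * gl$x, s + (8.5 - s) * gl$x)
  w <- c((s + 8.5) * gl$w, (8.5 - s) * gl$w) * stats::dnorm(z)
  list(z = z, w = w)
}

# Total-variance Gaussian average int Dz' phi(u + sqrt(sigma0) z').
phi_total_mean <- function(u, sigma0, nl, order = 48) {
  phi_inner_mean(u, sqrt(sigma0), nl, order)
}

#' Solve the static mean-field equations for u and q
#'
#' Given a candidate total variance `sigma0`, solves the coupled equations
#' `u = I0 - J0 sqrt(K) int Dz' phi(u + sqrt(sigma0) z')` and
#' `q = [<phi>^2]` with quenched sd `g K^(1/4) sqrt(q)` and temporal sd
#' `sqrt(sigma0 - g^2 sqrt(K) q)`. The `u` equation is strictly monotone and
#' is solved by bracketed root finding; `q` then follows by damped
#' fixed-point iteration (damping 0.5, tolerance 1e-10).
#'
#' @param sigma0 candidate total variance of `x`, `> 0`.
#' @param p a [dmft_params()].
#' @return list with `u`, `q`, `m` (mean response `(I0 - u)/(J0 sqrt(K))`),
#'   `clamped` (TRUE when the candidate made the temporal variance
#'   negative during iteration, i.e. `sigma0` inadmissible), `iterations`,
#'   and the self-consistency `residuals`.
#' @export
solve_uq <- function(sigma0, p) {
  stopifnot(inherits(p, "dmft_params"), sigma0 > 0)
  ord <- p$quad_order
  JK <- p$J0 * sqrt(p$K)
  h <- function(u) u - p$I0 + JK * phi_total_mean(u, sigma0, p$nl, ord)
  lo <- p$I0 - JK * max(1, phi_inner_mean(p$I0, sqrt(sigma0), p$nl, ord)) - 1
  u <- stats::uniroot(h, c(lo, p$I0 + 1), extendInt = "upX",
                      tol = .Machine$double.eps^0.75)$root
  m <- phi_total_mean(u, sigma0, p$nl, ord)

  gKq <- function(q) p$g^2 * sqrt(p$K) * q
  clamped <- FALSE
  q <- m^2
  it <- 0L
  repeat {
    it <- it + 1L
    tvar <- sigma0 - gKq(q)
    if (tvar < 0) { clamped <- TRUE; tvar <- 0 }
    da <- double_gaussian_average(p$nl, u, p$g * p$K^0.25 * sqrt(q),
                                  sqrt(tvar), p$quad_order)
    q_new <- 0.5 * q + 0.5 * da$meansq
    if (abs(q_new - q) < 1e-10 || it >= 10000L) { q <- q_new; break }
    q <- q_new
  }
  tvar <- max(sigma0 - gKq(q), 0)
  da <- double_gaussian_average(p$nl, u, p$g * p$K^0.25 * sqrt(q),
                                sqrt(tvar), p$quad_order)
  res <- c(u = abs(u - (p$I0 - JK * phi_total_mean(u, sigma0, p$nl, ord))),
           q = abs(q - da$meansq))
  if (it >= 10000L && res[["q"]] > 1e-8)
    stop(sprintf("solve_uq did not converge: residual %.3e", res[["q"]]))
  list(u = u, q = q, m = m, clamped = clamped, iterations = it,
       residuals = res)
}

# Lagged rate correlator [<phi(t) phi(t+tau)>] for autocovariance sigma of x:
# shared quenched load sqrt(|sigma|) z, independent temporal parts
# sqrt(sigma0 - |sigma|) xi, xi'.
dmft_correlator <- function(sigma, u, sigma0, p, order = p$quad_order) {
  s <- abs(sigma)
  tv <- max(sigma0 - s, 0)
  if (s == 0) return(phi_inner_mean(u, sqrt(tv), p$nl, order)^2)
  if (tv == 0 && p$nl$kind == "heaviside")
    return(phi_inner_mean(u, sqrt(s), p$nl, order))  # phi^2 = phi
  if (tv == 0 && !(p$nl$kind %in% c("heaviside", "linear")))
    return(kinked_gauss_mean(u, sqrt(s), phi_branch(p$nl, TRUE), order))
  sp <- split_normal_rule(-u / sqrt(s), order)
  inner <- phi_inner_mean(u + sqrt(s) * sp$z, sqrt(tv), p$nl, order)
  sum(sp$w * inner^2)
}

#' Evolve the autocorrelation equation of motion
#'
#' Integrates the autonomous second-order equation
#' `d^2 sigma / dtau^2 = sigma - g^2 sqrt(K) [<phi(t) phi(t+tau)>]` from
#' `sigma(0) = sigma0`, `dsigma/dtau = 0`, with the lagged correlator built
#' from the shared quenched component `sqrt(|sigma|) z` and independent
#' temporal components. Adaptive 5th-order explicit Runge-Kutta
#' (rel/abs tolerance 1e-9/1e-11). Admissibility of the candidate `sigma0`
#' is read off the trajectory: a valid autocorrelation must keep
#' `dsigma/dtau <= 0` and `sigma >= 0` throughout.
#'
#' @param u,q self-consistent statics at `sigma0` from [solve_uq()].
#' @param sigma0 candidate total variance.
#' @param p a [dmft_params()].
#' @param grid_dt output grid spacing in `tau`.
#' @return list with `tau`, `sigma`, `dsigma`, `C` (correlator along the
#'   path), and `violation`: `"none"` (decays cleanly to the quenched
#'   floor), `"crash"` (`sigma` driven below zero: `sigma0` too small),
#'   `"rebound"` (turns upward before settling on the floor: `sigma0` too
#'   large), `"runaway"` (immediate upward motion: `sigma0` above the
#'   zero-acceleration line, far too large), or `"stalled"` (no violation
#'   but still far from the floor at `tau_max`, near that same line: too
#'   large).
#' @export
evolve_sigma <- function(u, q, sigma0, p, grid_dt = 0.05) {
  gK <- p$g^2 * sqrt(p$K)
  rhs <- function(t, y, parms) {
    list(c(y[2], y[1] - gK * dmft_correlator(y[1], u, sigma0, p)))
  }
  times <- seq(0, p$tau_max, by = grid_dt)
  sol <- deSolve::ode(y = c(s = sigma0, v = 0), times = times, func = rhs,
                      parms = NULL, method = "ode45", rtol = 1e-9,
                      atol = 1e-11)
  s <- sol[, "s"]; v <- sol[, "v"]
  floor_var <- gK * q
  vtol <- 1e-7 * max(sigma0, 1)
  stol <- 1e-9 * max(sigma0, 1)
  bad_up <- which(v > vtol)
  bad_neg <- which(s < -stol)
  first_up <- if (length(bad_up)) bad_up[1] else Inf
  first_neg <- if (length(bad_neg)) bad_neg[1] else Inf
  violation <- if (is.infinite(first_up) && is.infinite(first_neg)) {
    # no violation on the horizon: either a genuine decay to the quenched
    # floor, or a stall near the zero-acceleration line sigma = g^2 sqrt(K)
    # C(sigma), where the decay is too slow to resolve (sigma0 too large)
    if (s[length(s)] - floor_var < 0.02 * max(sigma0 - floor_var, stol))
      "none" else "stalled"
  } else if (first_neg < first_up) {
    "crash"      # sigma driven below zero: sigma0 too small
  } else if (s[first_up] >= sigma0 * (1 - 1e-6)) {
    "runaway"    # immediate upward motion: above the zero-acceleration line
  } else {
    "rebound"    # turns upward before settling on the floor: sigma0 too large
  }
  cut <- min(first_up, first_neg, length(s))
  C <- vapply(s[seq_len(cut)], dmft_correlator, numeric(1),
              u = u, sigma0 = sigma0, p = p)
  list(tau = times[seq_len(cut)], sigma = s[seq_len(cut)],
       dsigma = v[seq_len(cut)], C = C, violation = violation,
       full = list(tau = times, sigma = s, dsigma = v))
}

#' Energy functional along a sigma trajectory
#'
#' The equation of motion for `sigma` is Newtonian,
#' `sigma'' = -dV/dsigma` with
#' `V(sigma) = -sigma^2/2 + g^2 sqrt(K) int C`, so
#' `E = (sigma')^2/2 + V(sigma)` is conserved along exact solutions; its
#' numerical drift measures integration error. The potential integral is
#' accumulated trapezoidally along the (monotone) path.
#'
#' @param path result of [evolve_sigma()].
#' @param p a [dmft_params()].
#' @return numeric vector of energies along the path (constant up to
#'   integration tolerance), normalized to start at 0.
#' @export
dmft_energy <- function(path, p) {
  gK <- p$g^2 * sqrt(p$K)
  W <- pracma::cumtrapz(path$sigma, path$C)
  E <- path$dsigma^2 / 2 - path$sigma^2 / 2 + gK * as.numeric(W)
  E - E[1]
}

#' Solve the dynamic mean-field theory
#'
#' Finds the self-consistent total variance `sigma0` by bisection: for each
#' candidate, the statics `(u, q)` are solved and the autocorrelation
#' equation evolved; candidates rejected as `"rebound"` are too small and
#' `"overshoot"` too large, and the admissible solution sits on the
#' boundary, where `sigma(tau)` decays monotonically to the quenched floor
#' `g^2 sqrt(K) q`. From the solution: mean response
#' `m = (I0 - u)/(J0 sqrt(K))`, active fraction
#' `f = Phi(u / sqrt(sigma0))`, synaptic-input autocorrelation
#' `R_eta(tau) = g^2 sqrt(K) (C(tau) - q)`, and decorrelation rate
#' `beta = R_eta(0) / int R_eta`.
#'
#' @param p a [dmft_params()].
#' @param sigma0_bracket optional length-2 bracket for `sigma0`; found by a
#'   coarse geometric scan when omitted.
#' @param max_iter bisection iteration cap.
#' @return an object of class `dmft_solution` with `u`, `m`, `q`, `sigma0`,
#'   `quenched_var`, `f`, `beta`, `tau`, `sigma`, `R_eta`, `residuals`, and
#'   the final `bracket`.
#' @export
dmft_solve <- function(p, sigma0_bracket = NULL, max_iter = 60) {
  stopifnot(inherits(p, "dmft_params"))
  classify <- function(s0) {
    uq <- solve_uq(s0, p)
    path <- evolve_sigma(uq$u, uq$q, s0, p)
    list(uq = uq, path = path, violation = path$violation)
  }
  too_small <- "crash"
  if (is.null(sigma0_bracket)) {
    # the sigma0 axis is ordered: crash region (too small) ... [chaotic
    # solution] ... rebound region ... stalled / runaway near the
    # zero-acceleration line (too large). Bracket the crash-to-rebound
    # transition.
    grid <- 10^seq(-3, 1.8, by = 0.3)
    cls <- character(length(grid))
    for (i in seq_along(grid)) cls[i] <- classify(grid[i])$violation
    if (any(cls == "none")) {
      s0 <- grid[which(cls == "none")[1]]
      bracket <- c(s0, s0)
    } else {
      trans <- which(cls[-length(cls)] == too_small &
                     cls[-1] %in% c("rebound", "runaway", "stalled"))
      if (!length(trans))
        stop("no admissible sigma0 bracket found: parameters appear to lie outside the chaotic regime")
      i <- trans[length(trans)]
      bracket <- c(grid[i], grid[i + 1])
    }
  } else bracket <- sigma0_bracket
  lo <- bracket[1]; hi <- bracket[2]
  best <- NULL
  for (it in seq_len(max_iter)) {
    if ((hi - lo) < 1e-8 * hi) break
    mid <- (lo + hi) / 2
    r <- classify(mid)
    if (r$violation == too_small) lo <- mid
    else { hi <- mid; best <- r }  # rebound or clean: hugs the floor longest
  }
  if (is.null(best)) best <- classify(hi)
  sigma0 <- hi
  uq <- best$uq; path <- best$path
  gK <- p$g^2 * sqrt(p$K)
  R_eta <- gK * (path$C - uq$q)
  beta <- R_eta[1] / pracma::trapz(path$tau, pmax(R_eta, 0))
  structure(list(params = p, u = uq$u, m = uq$m, q = uq$q,
                 sigma0 = sigma0, quenched_var = gK * uq$q,
                 f = pnorm(uq$u / sqrt(sigma0)),
                 tau = path$tau, sigma = path$sigma, dsigma = path$dsigma,
                 R_eta = R_eta, beta = beta,
                 residuals = uq$residuals, clamped = uq$clamped,
                 bracket = c(lo, hi), path = path),
            class = "dmft_solution")
}

#' @export
print.dmft_solution <- function(x, ...) {
  p <- x$params
  cat(sprintf("<dmft_solution> K = %g, J0 = %g, g = %g, I0 = %g, phi = %s\n",
              p$K, p$J0, p$g, p$I0, p$nl$kind))
  cat(sprintf("  u = %.5f, m = %.5g, q = %.5g, sigma0 = %.5f, f = %.5g, beta = %.4f\n",
              x$u, x$m, x$q, x$sigma0, x$f, x$beta))
  invisible(x)
}

#' Compare a DMFT solution with matched simulation statistics
#'
#' Relative errors of the mean response, active fraction and decorrelation
#' rate between the theory and a (seed-averaged) simulation summary at the
#' same parameters, plus an L2 distance between normalized synaptic-input
#' autocorrelations when one is supplied.
#'
#' @param solution a `dmft_solution`.
#' @param stats a one-row `data.frame` as from [summary_stats()] (or a
#'   seed-average of such rows) from a gaussian-weight simulation at matched
#'   `(J0, g, K, I0)`.
#' @param ac optional [autocorrelation()] result for the simulated `eta`.
#' @return list of relative errors `m`, `f`, `beta`, and `R_l2` when `ac`
#'   given.
#' @export
compare_to_simulation <- function(solution, stats, ac = NULL) {
  stopifnot(inherits(solution, "dmft_solution"))
  p <- solution$params
  for (fld in c("J0", "g", "K", "I0")) {
    if (!is.null(stats[[fld]]) && !is.na(stats[[fld]]) &&
        abs(stats[[fld]] - p[[fld]]) > 1e-9)
      stop(sprintf("parameter mismatch in '%s': simulation %g vs theory %g",
                   fld, stats[[fld]], p[[fld]]))
  }
  out <- list(m = abs(solution$m - stats$phi_bar) / abs(stats$phi_bar),
              f = abs(solution$f - stats$f) / abs(stats$f),
              beta = abs(solution$beta - stats$beta) / abs(stats$beta))
  if (!is.null(ac)) {
    Rn_sim <- ac$R / ac$R[1]
    Rn_th <- stats::approx(solution$tau, solution$R_eta / solution$R_eta[1],
                           xout = ac$lag, rule = 2)$y
    out$R_l2 <- sqrt(mean((Rn_sim - Rn_th)^2))
  }
  out
}
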
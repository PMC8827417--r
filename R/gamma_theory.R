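#' Gamma-distribution parameters of the recurrent synaptic input
#'
#' For gamma-family weights and Heaviside (binary) rates, the recurrent
#' input is a sum of `f * K` i.i.d. gamma(`kappa`, `theta`) weights, and is
#' therefore itself gamma-distributed with shape `alpha = f * K * kappa` and
#' the same scale `theta`. The implied mean is `J0 * f * sqrt(K)` and
#' variance `g^2 * f * K^(1 - nu)`. With `nu = 1/2` and `f` proportional to
#' `1/sqrt(K)` both `alpha` and `theta` are K-independent, so the input
#' distribution does not narrow with K and stays non-Gaussian. For
#' non-Heaviside rates these are approximations.
#'
#' @param f fraction of active units, `0 < f <= 1` (`f = 0` signals the
#'   degenerate point-mass at 0).
#' @param spec a gamma-family [weight_spec()].
#' @return list with `alpha`, `theta`, `mean`, `var`, and `degenerate`.
#' @export
eta_distribution_params <- function(f, spec) {
  stopifnot(inherits(spec, "weight_spec"), spec$family == "gamma",
            is.numeric(f), length(f) == 1L, f >= 0, f <= 1)
  if (f == 0) {
    warning("f = 0: recurrent input is a point mass at 0")
    return(list(alpha = 0, theta = NA_real_, mean = 0, var = 0,
                degenerate = TRUE))
  }
  p <- gamma_weight_params(spec)
  list(alpha = f * spec$K * p[["kappa"]], theta = p[["theta"]],
       mean = spec$J0 * f * sqrt(spec$K),
       var = spec$g^2 * f * spec$K^(1 - spec$nu),
       degenerate = FALSE)
}

#' Mean-current balance relation
#'
#' Averaging the rate equation over units and time gives
#' `x_bar = I0 - J0 * f * sqrt(K)`: the mean total current is the bias minus
#' the mean recurrent input. Keeping `x_bar` of order 1 at large `K` forces
#' `f ~ 1/sqrt(K)` — sparsity replaces current cancellation as the balancing
#' mechanism.
#'
#' @param f fraction of active units.
#' @param J0 mean-coupling scale.
#' @param K in-degree.
#' @param I0 bias current.
#' @return predicted mean total current `x_bar`.
#' @seealso [predicted_f()], its inverse.
#' @export
balance_relation <- function(f, J0, K, I0) {
  stopifnot(K >= 1)
  I0 - J0 * f * sqrt(K)
}

#' Active fraction implied by the balance relation
#'
#' Inverts [balance_relation()]: `f = (I0 - x_bar) / (J0 * sqrt(K))`. Exact
#' for Heaviside rates, where `f = phi_bar`.
#'
#' @param x_bar mean total current.
#' @inheritParams balance_relation
#' @return predicted active fraction.
#' @export
predicted_f <- function(x_bar, J0, K, I0) {
  stopifnot(K >= 1)
  (I0 - x_bar) / (J0 * sqrt(K))
}

#' Gaussian-proximity diagnostic for the input distribution
#'
#' The shape parameter of the recurrent-input gamma distribution,
#' `f * K * kappa = f * (J0^2 / g^2) * K^nu`. A gamma distribution is close
#' to Gaussian once its shape is about 20 or larger; in the high-variance
#' regime (`nu = 1/2`, `f ~ 1/sqrt(K)`) the shape is K-independent and the
#' input stays non-Gaussian, while in the low-variance regime it grows like
#' `K`.
#'
#' @inheritParams eta_distribution_params
#' @return list with `shape` and logical `approx_gaussian` (`shape >= 20`).
#' @export
eta_shape_diagnostic <- function(f, spec) {
  stopifnot(inherits(spec, "weight_spec"), spec$family == "gamma")
  p <- gamma_weight_params(spec)
  shape <- f * spec$K * p[["kappa"]]
  list(shape = shape, approx_gaussian = shape >= 20)
}
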
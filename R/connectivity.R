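#' Specify a synaptic weight distribution
#'
#' A weight specification fixes the family of the synaptic-strength
#' distribution together with the moment scalings in the in-degree `K`:
#' nonzero weights have mean `J0 / sqrt(K)` and variance `g^2 / K^nu`. The
#' exponent `nu` selects the regime: `nu = 1/2` is the high-variance
#' (sparse-balance) scaling, `nu = 1` the conventional low-variance scaling.
#'
#' @param family one of `"gamma"`, `"lognormal"`, `"gaussian"`, `"binary"`.
#'   All families except `"gaussian"` have nonnegative support; the binary
#'   family is a two-point law on `{0, w}`.
#' @param J0 mean-coupling scale, order 1, `> 0`.
#' @param g variance-coupling scale, order 1, `>= 0` (`g = 0` gives the
#'   degenerate all-equal-weights limit).
#' @param nu variance-scaling exponent in `(0, 1]`.
#' @param K in-degree: number of structurally nonzero weights per row.
#' @param N network size, `>= K`; defaults to `K` (dense connectivity).
#' @return an object of class `weight_spec`.
#' @seealso [sample_weights()], [weight_moments()]
#' @examples
#' spec <- weight_spec("gamma", J0 = 2, g = 2, nu = 1/2, K = 1000)
#' weight_moments(spec)
#' @export
weight_spec <- function(family = c("gamma", "lognormal", "gaussian", "binary"),
                        J0, g, nu = 0.5, K, N = K) {
  family <- match.arg(family)
  stopifnot(is.numeric(J0), length(J0) == 1L, J0 > 0,
            is.numeric(g), length(g) == 1L, g >= 0,
            is.numeric(nu), length(nu) == 1L, nu > 0, nu <= 1,
            is.numeric(K), length(K) == 1L, K >= 1, K == round(K),
            is.numeric(N), length(N) == 1L, N >= K, N == round(N))
  structure(list(family = family, J0 = J0, g = g, nu = nu,
                 K = as.integer(K), N = as.integer(N)),
            class = "weight_spec")
}

#' Target moments of the nonzero weights
#'
#' @param spec a [weight_spec()].
#' @return named vector with the population mean `J0 / sqrt(K)` and variance
#'   `g^2 / K^nu` of the nonzero weights.
#' @export
weight_moments <- function(spec) {
  stopifnot(inherits(spec, "weight_spec"))
  c(mean = spec$J0 / sqrt(spec$K), var = spec$g^2 / spec$K^spec$nu)
}

#' Shape and scale of gamma-family weights
#'
#' For the gamma family the two target moments fix the shape
#' `kappa = (J0^2 / g^2) * K^(nu - 1)` and scale
#' `theta = (g^2 / J0) * K^(1/2 - nu)`, so that
#' `kappa * theta = J0 / sqrt(K)` and `kappa * theta^2 = g^2 / K^nu`.
#'
#' @param spec a [weight_spec()] with positive `g`.
#' @return named vector `c(kappa, theta)`.
#' @export
gamma_weight_params <- function(spec) {
  stopifnot(inherits(spec, "weight_spec"), spec$g > 0)
  c(kappa = (spec$J0^2 / spec$g^2) * spec$K^(spec$nu - 1),
    theta = (spec$g^2 / spec$J0) * spec$K^(0.5 - spec$nu))
}

# i.i.d. draws from the nonzero-weight distribution of `spec`
draw_weights <- function(spec, n) {
  m <- spec$J0 / sqrt(spec$K)
  v <- spec$g^2 / spec$K^spec$nu
  if (v == 0) return(rep(m, n))
  switch(spec$family,
    gamma = {
      p <- gamma_weight_params(spec)
      rgamma(n, shape = p[["kappa"]], scale = p[["theta"]])
    },
    lognormal = {
      s2 <- log1p(v / m^2)
      rlnorm(n, meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
    },
    gaussian = rnorm(n, mean = m, sd = sqrt(v)),
    binary = {
      # two-point {0, w}: w and P(w) solved from the first two moments;
      # P(w) = m^2 / (m^2 + v) <= 1 always, so the law is feasible
      w <- (v + m^2) / m
      p <- m / w
      w * (runif(n) < p)
    })
}

#' Sample a synaptic weight matrix
#'
#' Draws an `N x N` coupling matrix whose rows each contain exactly `K`
#' structurally nonzero entries, i.i.d. from the distribution fixed by
#' `spec` (mean `J0/sqrt(K)`, variance `g^2/K^nu`). When `K = N` the matrix
#' is dense and self-couplings are sampled like any other entry. For `K < N`
#' the nonzero positions per row are uniform without replacement (exact
#' in-degree, not Bernoulli dilution).
#'
#' @param spec a [weight_spec()].
#' @param seed integer RNG seed; recorded in the result for reproducibility.
#' @return an object of class `weight_matrix`: list with elements `values`
#'   (`N x N` numeric matrix), `spec`, and `seed`.
#' @examples
#' W <- sample_weights(weight_spec("gamma", J0 = 2, g = 2, K = 50), seed = 1)
#' range(rowSums(W$values != 0))
#' @export
sample_weights <- function(spec, seed) {
  stopifnot(inherits(spec, "weight_spec"))
  set.seed(seed)
  N <- spec$N; K <- spec$K
  if (K == N) {
    values <- matrix(draw_weights(spec, N * N), N, N)
  } else {
    values <- matrix(0, N, N)
    cols <- vapply(seq_len(N), function(i) sample.int(N, K), integer(K))
    idx <- cbind(rep(seq_len(N), each = K), as.vector(cols))
    values[idx] <- draw_weights(spec, N * K)
  }
  structure(list(values = values, spec = spec, seed = as.integer(seed)),
            class = "weight_matrix")
}

#' @export
print.weight_matrix <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<weight_matrix> %d x %d, family = %s, J0 = %g, g = %g, nu = %g, K = %d, seed = %d\n",
              s$N, s$N, s$family, s$J0, s$g, s$nu, s$K, x$seed))
  invisible(x)
}

#' Exact in-degree dilution mask
#'
#' Binary `N x N` matrix with exactly `K` ones per row at uniformly random
#' column positions. Used to restrict connectivity to `K < N` presynaptic
#' partners per unit while keeping the in-degree exact.
#'
#' @param N network size.
#' @param K in-degree, `<= N`.
#' @param seed integer RNG seed.
#' @return integer 0/1 matrix with row sums all equal to `K`.
#' @export
dilute_mask <- function(N, K, seed) {
  stopifnot(K >= 1, K <= N)
  set.seed(seed)
  mask <- matrix(0L, N, N)
  if (K == N) {
    mask[] <- 1L
  } else {
    cols <- vapply(seq_len(N), function(i) sample.int(N, K), integer(K))
    mask[cbind(rep(seq_len(N), each = K), as.vector(cols))] <- 1L
  }
  mask
}

#' Build a signed two-population E-I coupling matrix
#'
#' Constructs the `(NE + NI) x (NE + NI)` coupling matrix of an
#' excitatory-inhibitory network. Every unit receives exactly `K` nonzero
#' weights from each population, so its total in-degree is `2K`, and the
#' moment scalings are referenced to that total: block `ab` (postsynaptic
#' `a`, presynaptic `b`) has per-weight mean `J[ab] / sqrt(2K)` and variance
#' `g^2 / (2K)^nu` (high-variance scaling by default). Referencing the
#' moments to the total in-degree is what reproduces the two-population
#' activity levels of the single-`K`-parameter network description.
#' Excitatory columns enter the dynamics with a `+` sign, inhibitory columns
#' with a `-` sign; the sign is stored in the matrix so that the network
#' update is `dx = -x + W phi(x) + I`.
#'
#' @param J named numeric vector of block coupling scales with names
#'   `EE`, `EI`, `IE`, `II` (postsynaptic population first); all `>= 0`,
#'   a zero scale giving an empty block.
#' @param g shared variance-coupling scale.
#' @param NE,NI population sizes.
#' @param K in-degree from each presynaptic population; `<= NE` and `<= NI`.
#' @param family nonzero-weight family (see [weight_spec()]); `"gaussian"`
#'   is disallowed here because block signs must be carried by the column
#'   sign, not by the samples.
#' @param nu variance-scaling exponent, default `1/2`.
#' @param seed integer RNG seed.
#' @return a `weight_matrix` with additional fields `NE`, `NI`,
#'   `labels` (factor of `"E"`/`"I"` per unit), `J_blocks`, and
#'   `signed = TRUE`.
#' @export
build_ei_matrix <- function(J = c(EE = 1, EI = 2, IE = 1, II = 1.2),
                            g = 1, NE, NI, K,
                            family = c("gamma", "lognormal", "binary"),
                            nu = 0.5, seed = 1L) {
  family <- match.arg(family)
  stopifnot(all(c("EE", "EI", "IE", "II") %in% names(J)),
            all(J >= 0), g >= 0, K >= 1, K <= NE, K <= NI)
  set.seed(seed)
  N <- NE + NI
  values <- matrix(0, N, N)
  rows <- list(E = seq_len(NE), I = NE + seq_len(NI))
  cols <- list(E = seq_len(NE), I = NE + seq_len(NI))
  npre <- c(E = NE, I = NI)
  for (post in c("E", "I")) for (pre in c("E", "I")) {
    Jab <- J[[paste0(post, pre)]]
    if (Jab == 0) next
    # rescaled (J0, g) give per-weight mean Jab/sqrt(2K) and variance
    # g^2/(2K)^nu, i.e. moments referenced to the total in-degree 2K
    bspec <- weight_spec(family, J0 = Jab / sqrt(2), g = g / 2^(nu / 2),
                         nu = nu, K = K, N = npre[[pre]])
    ri <- rows[[post]]
    pick <- vapply(ri, function(i) sample.int(npre[[pre]], K), integer(K))
    w <- draw_weights(bspec, length(ri) * K)
    if (pre == "I") w <- -w
    values[cbind(rep(ri, each = K), cols[[pre]][as.vector(pick)])] <- w
  }
  structure(list(values = values,
                 spec = list(family = family, g = g, nu = nu, K = as.integer(K),
                             N = as.integer(N)),
                 J_blocks = J, NE = as.integer(NE), NI = as.integer(NI),
                 labels = factor(rep(c("E", "I"), c(NE, NI))),
                 signed = TRUE, seed = as.integer(seed)),
            class = "weight_matrix")
}

#' Write a weight matrix to CSV
#'
#' Dense CSV of the coupling values preceded by commented header lines
#' carrying the sampling metadata (family, J0, g, nu, K, N, seed), so small
#' fixtures are self-describing plain text.
#'
#' @param W a `weight_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_weight_csv <- function(W, path) {
  stopifnot(inherits(W, "weight_matrix"))
  s <- W$spec
  hdr <- sprintf("# family=%s g=%g nu=%g K=%d N=%d seed=%d",
                 s$family, s$g, s$nu, s$K, s$N, W$seed)
  if (!is.null(s$J0)) hdr <- paste0(hdr, sprintf(" J0=%g", s$J0))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(W$values, con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
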
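---
title: "Sparse balance: model, statistics and mean-field methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse balance: model, statistics and mean-field methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sparsebalance)
```

## The model

`sparsebalance` simulates and analyses recurrent rate networks in which an
order-one feedforward bias current is combined with broadly distributed
synaptic weights. The single-population network is inhibitory: currents
$x_i$ and rates $\phi(x_i)$ obey

$$\tau_x \frac{dx_i}{dt} = -x_i - \sum_{j=1}^N J_{ij}\,\phi(x_j) + I_0,
\qquad J_{ij} \ge 0,$$

with time measured in units of $\tau_x = 1$. The rate function is
rectified: zero at and below threshold ($x \le 0$), and $\tanh(x)$,
$x^\lambda$, or the Heaviside step above it. Each row of $J$ has exactly
$K$ structurally nonzero entries drawn i.i.d. with mean $J_0/\sqrt{K}$ and
variance $g^2/K^\nu$. The exponent $\nu$ selects the regime:

* $\nu = 1$ ("low variance") is the conventional scaling. With the usual
  $\sqrt{K}$-strong bias replaced by an order-one $I_0$, activity stays
  dense but individual rates vanish as $K$ grows.
* $\nu = 1/2$ ("high variance") is the sparse-balance regime: the summed
  variance of the roughly $fK$ active inputs stays order one, chaotic
  fluctuations survive, and the order-one constraint on the mean current
  $\bar{x} = I_0 - J_0 f \sqrt{K}$ is met by the *sparsity* $f \sim
  1/\sqrt{K}$ rather than by excitatory-inhibitory cancellation. Individual
  active units keep order-one rates.

Weight families: `gamma` (the analytically convenient choice: shape
$\kappa = (J_0^2/g^2)K^{\nu-1}$, scale $\theta = (g^2/J_0)K^{1/2-\nu}$),
`lognormal` and `binary` (two-point $\{0, w\}$), all nonnegative, and
`gaussian` (not sign-constrained; the mean-field reference case). Moments,
not shapes, are what the theory pins down; the regime's behaviour is the
same across families.

## What each statistic measures

All statistics are computed from burn-in-free trajectories; averages over
units are written $[\cdot]$, over time $\langle\cdot\rangle$.

* `mean_response` $\bar\phi$, `fraction_active` $f$ (strictly $\phi > 0$;
  a unit exactly at threshold counts as inactive), `active_mean`
  $\mu = \bar\phi / f$, so $\bar\phi = f\mu$ holds to machine precision.
* `variance_decomposition`: population (1/n) conventions throughout, so
  the temporal + quenched split of the pooled variance is exact rather
  than approximate. Quenched variance measures the spread of per-unit time
  averages (frozen disorder); temporal variance the fluctuations around
  them.
* `autocorrelation`: per-unit autocovariance about per-unit means, FFT
  based, biased (1/n) estimator so that $R(0)$ equals the temporal
  variance exactly. `correlation_time` integrates $R$ trapezoidally from
  lag zero to its first zero crossing — the infinite upper limit of the
  defining integral is unreachable on a finite window, and beyond the
  first crossing a chaotic network's $R$ is noise. `decorrelation_rate`
  is $\beta = \tau_x/\tau_\eta$; it grows like $\log K$ in sparse balance.
* `balance_index` $\chi = \bar{x}/I_0$: order 1 in sparse balance,
  shrinking with $K$ in conventional balance.
* `synchrony_index`: the chi-squared population-variance ratio (variance
  of the population-mean trace over mean per-unit variance). It is
  computed on the **rates** by default. The choice matters: on currents
  the index at the asynchronous working point is a few $10^{-3}$ (weak
  common-input correlations survive in $x$), while on rates it sits at
  the $10^{-4}$ asynchronous floor that the regime is known for. The
  current-based variant remains available via `which = "x"`.
* `psi_ratio` $\psi = \overline{\phi^2}/\bar\phi$: implemented as the
  second-to-first moment ratio of the rates, which reduces to $\mu$-like
  quantities for binary rates (1 for the Heaviside).
* `gaussianity_report`: moment shape statistics plus an Anderson-Darling
  normality statistic on an evenly thinned subsample (capped at a fixed
  size so runs of different lengths are comparable); in the high-variance
  regime the pooled current distribution is left-skewed, non-Gaussian,
  with mean below threshold.

## Gamma closure of the recurrent input

For Heaviside units and gamma weights, the recurrent input
$\eta_i = \sum_j J_{ij}\phi(x_j)$ is a sum of $fK$ i.i.d. gamma variables
with shared scale, hence itself gamma with shape $\alpha = fK\kappa$ and
scale $\theta$: mean $J_0 f\sqrt{K}$, variance $g^2 f K^{1-\nu}$. At
$\nu = 1/2$ with $f \propto 1/\sqrt{K}$ both parameters are
$K$-independent — the input distribution does not narrow with $K$, and
since $\alpha$ stays order one (far below the $\sim 20$ needed for a gamma
to look Gaussian) the input stays non-Gaussian at any $K$. Sparsity is
instead produced dynamically: fluctuations speed up with $K$, the unit's
low-pass filter transmits less of them to $x$, and the above-threshold
mass shrinks. `eta_distribution_params`, `balance_relation` and
`eta_shape_diagnostic` expose these predictions; they are exact only for
Heaviside rates and exposed as approximations otherwise.

## Dynamic mean-field theory

For Gaussian weights the network admits a standard DMFT closure. The
single-unit current decomposes into a mean $u = I_0 - J_0\sqrt{K}m$, a
quenched Gaussian component of variance $g^2\sqrt{K}q$ (note the
$\sqrt{K}$, inherited from the high-variance scaling) and a temporal
component of variance $\sigma_0 - g^2\sqrt{K}q$, with $m = [\langle\phi\rangle]$
and $q = [\langle\phi\rangle^2]$. The autocovariance $\sigma(\tau)$ of $x$
obeys the Newtonian equation
$\ddot\sigma = \sigma - g^2\sqrt{K}\,[\langle\phi(t)\phi(t+\tau)\rangle]$
with $\sigma(0) = \sigma_0$, $\dot\sigma(0) = 0$, where the lagged
correlator shares the quenched load $\sqrt{|\sigma|}z$ between the two time
points. From a solution: $f = \Phi(u/\sqrt{\sigma_0})$,
$R_\eta = g^2\sqrt{K}(C(\sigma) - q)$, and $\beta$ as the normalized
inverse area under $R_\eta$.

Numerical choices, and why:

* **Quadrature.** The rectified nonlinearities are continuous but kinked
  at threshold, which destroys the spectral accuracy of naive
  Gauss-Hermite rules. All Gaussian averages therefore integrate only the
  smooth positive branch, with Gauss-Legendre nodes between the kink and
  an 8.5-sd tail cutoff; outer (quenched) integrals use two panels split
  at the transition point $z^* = -u/\text{(quenched sd)}$. With this
  scheme, doubling the order moves $u$ and $q$ by less than $10^{-6}$.
  Heaviside inner integrals use the normal-CDF closed form.
* **Statics.** The $u$-equation is strictly monotone in $u$, so it is
  solved by bracketed root finding rather than damped iteration (the
  fixed-point map has Jacobian up to $J_0\sqrt{K}\,E[\phi']$ and can
  diverge under any fixed damping); $q$ then follows by damped (0.5)
  fixed-point iteration to $10^{-10}$.
* **The $\sigma_0$ bisection.** The equation of motion conserves an
  energy, and the admissible autocorrelation is the trajectory that rolls
  from $\sigma_0$ at rest and settles asymptotically on the quenched
  floor $g^2\sqrt{K}q$. Candidates below the solution crash through the
  floor toward $\sigma < 0$ ("crash"); candidates above it either turn
  upward before settling ("rebound"), run away upward immediately when
  $\sigma_0$ exceeds the zero-acceleration line $\sigma = g^2\sqrt{K}
  C(\sigma)$ ("runaway"), or creep too slowly to classify within the
  horizon ("stalled" — treated as too large, which is what prevents the
  bisection from collapsing onto the static zero-acceleration line
  instead of the chaotic solution). Bisection runs between crash and
  not-crash to relative width $10^{-8}$; the returned trajectory is the
  not-crash side, truncated at its first admissibility violation. The
  evolution uses adaptive RK45 (`deSolve::ode`, `ode45`, rtol/atol
  $10^{-9}/10^{-11}$) on a 0.05-spaced output grid; energy conservation
  along the path is checked in the tests up to the trapezoidal quadrature
  of the potential on that grid ($\sim 10^{-4}$ relative).
* The theory is solved for the Gaussian-weight network only (the
  sign-constrained families have no Gaussian closure); matching
  simulations for comparison must use `family = "gaussian"`.

## Integration and reproducibility

Plain forward Euler (the standard choice for these rate models), default
`dt = 0.02` with a hard cap at 0.05; chaotic-attractor statistics are
insensitive to halving `dt` (tested). Initial currents are
$0.1\,\mathcal{N}(0,1)$ — the attractor's statistics are
initial-condition independent, which the seed-swap test verifies. Default
burn-in 100 $\tau_x$; recording keeps at least 10 samples per $\tau_x$ so
that $\tau_\eta$ (often well below $\tau_x$ at large $K$) is resolved.
Every sampler takes an explicit seed that is recorded in its output, and
the full pipeline is reproducible seed-to-statistics. Divergence (possible
for supralinear $\phi$) aborts with the failing step rather than clipping.

The integrator core accumulates the recurrent drive over *active* columns
only, so a step costs $O(fN^2)$ rather than $O(N^2)$ — in the sparse
regime this is a 10-30x saving and is what makes the $K$-sweeps below
desk-scale.

## The E-I network

The two-population network (`build_ei_matrix`, `simulate_ei`) uses the
same per-weight rules per block, with excitatory columns entering with
$+$ and inhibitory with $-$ sign, block scales $J_{EE}, J_{EI}, J_{IE},
J_{II}$ (postsynaptic index first), one shared $g$, and population biases
$I_E$, $I_I$. Each unit receives exactly $K$ nonzero weights from each
population; because its *total* in-degree is then $2K$, the weight
moments are referenced to $2K$: mean $J_{ab}/\sqrt{2K}$, variance
$g^2/(2K)^\nu$. This is the reading consistent with the definition of $K$
as the number of inputs per neuron, and it is the one that reproduces the
two-population activity levels (about 10% of excitatory and 20-30% of
inhibitory units instantaneously active at the standard working point,
with about 2% / 15% of units above threshold more than half the time);
referencing the moments to $K$ per block underestimates all four numbers,
and drawing only $K$ total inputs per row overestimates them.

## What the tests do and do not show

The test suite checks the regime's signatures at desk scale: sweeps over
$K \in \{250, \dots, 4000\}$ with $N = K$, three seeds per point, recorded
windows of 400-500 $\tau_x$ at `dt = 0.05`, one E-I run at
$N_E = N_I = 3000$, $K = 600$, and DMFT-simulation comparisons at
$K \in \{400, 1600\}$ over five seeds. These sizes give the fitted
$1/\sqrt{K}$ exponents to about $\pm 0.05$ and stochastic fractions to a
few percent relative. The synthetic networks are exactly the model: random
unstructured connectivity, identical units, no noise (all variability is
deterministic chaos plus quenched disorder). Passing tests therefore show
the implementation reproduces the model's behaviour — they say nothing
about structured or correlated cortical connectivity, spiking dynamics,
or any biological data.

## Known limitations

* The DMFT bracket scan assumes the chaotic regime; at parameters with a
  stable fixed point it errors out rather than returning the fixed-point
  solution.
* `correlation_time` on short windows is biased by the first-zero-cross
  truncation when $R$ has a slow positive tail; the sweep defaults keep
  windows at least 40 times the largest observed $\tau_\eta$.
* Gamma-closure predictions are exact for Heaviside rates only.
* Serialization is plain CSV; trajectory stores are in-memory matrices,
  so very long high-resolution recordings of large networks should
  increase `record_stride`.
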
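// Forward-Euler integration core for rate networks
//
//   tau_x dx/dt = -x + M phi(x) + bias,   tau_x = 1
//
// M carries the sign with which each presynaptic column enters the dynamics
// (negative columns for inhibitory couplings). Because phi is rectified,
// phi(x) is zero for every sub-threshold unit; the recurrent drive is
// accumulated only over active columns, so the per-step cost is ~ f*N^2
// rather than N^2, a large saving in the sparse regime.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

enum PhiKind { PHI_HEAVISIDE = 0, PHI_RECT_TANH = 1, PHI_RECT_POWER = 2, PHI_LINEAR = 3 };

static inline double phi_scalar(double x, int kind, double lambda) {
  if (kind == PHI_LINEAR) return x;
  if (x <= 0.0) return 0.0;
  switch (kind) {
  case PHI_HEAVISIDE: return 1.0;
  case PHI_RECT_TANH: return std::tanh(x);
  default:            return (lambda == 1.0) ? x : std::pow(x, lambda);
  }
}

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(const arma::mat& M, int phi_kind, double lambda,
              const arma::vec& bias, double dt,
              int burn_steps, int n_steps, int stride,
              arma::vec x, bool record_drive) {
  const arma::uword N = M.n_rows;
  if (M.n_cols != N) stop("coupling matrix must be square");
  if (x.n_elem != N || bias.n_elem != N) stop("state/bias length mismatch");
  const int n_rec = (n_steps + stride - 1) / stride;

  arma::mat X(N, n_rec);
  arma::mat S;
  if (record_drive) S.set_size(N, n_rec);
  arma::vec times(n_rec);
  arma::vec drive(N), phi(N);

  int k = 0;
  const long total = (long)burn_steps + (long)n_steps;
  for (long t = 0; t < total; ++t) {
    if (phi_kind == PHI_LINEAR) {
      drive = M * x;
    } else {
      drive.zeros();
      for (arma::uword j = 0; j < N; ++j) {
        const double xj = x[j];
        if (xj > 0.0) {
          const double pj = phi_scalar(xj, phi_kind, lambda);
          const double* cj = M.colptr(j);
          double* d = drive.memptr();
          for (arma::uword i = 0; i < N; ++i) d[i] += pj * cj[i];
        }
      }
    }
    x += dt * (bias - x + drive);

    if (((t & 255L) == 0L || t == total - 1) && !x.is_finite())
      stop("non-finite network state at integration step %ld (t = %.2f tau_x): dynamics diverged",
           t, (double)(t + 1) * dt);

    const long s = t - (long)burn_steps;
    if (s >= 0 && s % stride == 0 && k < n_rec) {
      X.col(k) = x;
      if (record_drive) S.col(k) = drive;
      times[k] = (double)(s + 1) * dt;
      ++k;
    }
  }
  if (!x.is_finite())
    stop("non-finite network state at the final integration step: dynamics diverged");

  List out = List::create(_["x"] = X, _["times"] = times);
  if (record_drive) out["drive"] = S;
  return out;
}
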
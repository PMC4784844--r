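// Batched energy-descent relaxation of predictive-estimator states.
// Forward Euler on dr/dt = -(k1/2) dE/dr with a backtracking guard that
// halves any step increasing E, so the recorded energy trace is
// non-increasing by construction.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;

static inline double prior_energy(const mat& R, double a, double s0) {
  return a * arma::accu(arma::log1p(arma::square(R / s0)));
}

// Level-1-only relaxation (no top-down). Columns of I are independent
// module inputs; Msk is a 0/1 matrix of the same shape multiplying the
// bottom-up residual.
// [[Rcpp::export]]
List relax_l1_cpp(const arma::mat& I, const arma::mat& U, const arma::mat& Msk,
                  double alpha, double prior_scale, double k1, double sigma2,
                  double step, double tol, int max_iter, bool record_energy,
                  arma::mat R) {
  const double c_bu = k1 / sigma2;
  mat Res = Msk % (I - U * R);
  const double s0sq = prior_scale * prior_scale;
  double E = arma::accu(arma::square(Res)) / sigma2 + prior_energy(R, alpha, prior_scale);
  std::vector<double> trace;
  if (record_energy) trace.push_back(E);
  bool converged = false;
  int it = 0;
  double gmax = 0.0;
  for (; it < max_iter; ++it) {
    mat D = c_bu * (U.t() * Res) - (k1 * alpha) * (R / (s0sq + arma::square(R)));
    gmax = D.n_elem ? arma::abs(D).max() : 0.0;
    if (gmax <= tol) { converged = true; break; }
    double s = step;
    bool accepted = false;
    mat Rn, Resn;
    double En = E;
    while (s > step * 1e-8) {
      Rn = R + s * D;
      Resn = Msk % (I - U * Rn);
      En = arma::accu(arma::square(Resn)) / sigma2 + prior_energy(Rn, alpha, prior_scale);
      if (En <= E + 1e-12) { accepted = true; break; }
      s *= 0.5;
    }
    if (!accepted) break;  // stalled: cannot decrease E further
    R = std::move(Rn);
    Res = std::move(Resn);
    E = En;
    if (record_energy) trace.push_back(E);
  }
  return List::create(_["R"] = R, _["iterations"] = it,
                      _["converged"] = converged, _["grad_norm"] = gmax,
                      _["energy"] = E,
                      _["E_trace"] = record_energy ? wrap(trace) : R_NilValue);
}

// Joint two-level relaxation. I holds n_win consecutive columns per patch
// (d1 x (n_win * n)); R1 matches I's column layout (K1 x (n_win * n));
// R2 is K2 x n. U2 is (n_win * K1) x K2; reshaping R1 column-major stacks
// each patch's modules into r_cat.
// [[Rcpp::export]]
List relax_joint_cpp(const arma::mat& I, const arma::mat& U1,
                     const arma::mat& U2, const arma::mat& Msk,
                     double alpha1, double alpha2,
                     double prior_scale1, double prior_scale2,
                     double k1, double sigma2, double sigma2_td,
                     double step, double tol, int max_iter,
                     bool record_energy, arma::mat R1, arma::mat R2) {
  const arma::uword K1 = U1.n_cols;
  const arma::uword n = R2.n_cols;
  const arma::uword n_win = R1.n_cols / n;
  const double c_bu = k1 / sigma2;
  const double c_td = k1 / sigma2_td;
  const double s1sq = prior_scale1 * prior_scale1;
  const double s2sq = prior_scale2 * prior_scale2;

  auto energy = [&](const mat& Res1, const mat& Res2, const mat& A1,
                    const mat& A2) {
    return arma::accu(arma::square(Res1)) / sigma2 +
           arma::accu(arma::square(Res2)) / sigma2_td +
           prior_energy(A1, alpha1, prior_scale1) +
           prior_energy(A2, alpha2, prior_scale2);
  };

  mat Res1 = Msk % (I - U1 * R1);
  mat Rcat = arma::reshape(R1, K1 * n_win, n);
  mat Res2 = Rcat - U2 * R2;
  double E = energy(Res1, Res2, R1, R2);
  std::vector<double> trace;
  if (record_energy) trace.push_back(E);
  bool converged = false;
  int it = 0;
  double gmax = 0.0;
  for (; it < max_iter; ++it) {
    mat D1 = c_bu * (U1.t() * Res1) -
             c_td * arma::reshape(Res2, K1, n_win * n) -
             (k1 * alpha1) * (R1 / (s1sq + arma::square(R1)));
    mat D2 = c_td * (U2.t() * Res2) -
             (k1 * alpha2) * (R2 / (s2sq + arma::square(R2)));
    gmax = std::max(D1.n_elem ? arma::abs(D1).max() : 0.0,
                    D2.n_elem ? arma::abs(D2).max() : 0.0);
    if (gmax <= tol) { converged = true; break; }
    double s = step;
    bool accepted = false;
    mat R1n, R2n, Res1n, Res2n;
    double En = E;
    while (s > step * 1e-8) {
      R1n = R1 + s * D1;
      R2n = R2 + s * D2;
      Res1n = Msk % (I - U1 * R1n);
      Res2n = arma::reshape(R1n, K1 * n_win, n) - U2 * R2n;
      En = energy(Res1n, Res2n, R1n, R2n);
      if (En <= E + 1e-12) { accepted = true; break; }
      s *= 0.5;
    }
    if (!accepted) break;
    R1 = std::move(R1n);
    R2 = std::move(R2n);
    Res1 = std::move(Res1n);
    Res2 = std::move(Res2n);
    E = En;
    if (record_energy) trace.push_back(E);
  }
  return List::create(_["R"] = R1, _["R2"] = R2, _["iterations"] = it,
                      _["converged"] = converged, _["grad_norm"] = gmax,
                      _["energy"] = E,
                      _["E_trace"] = record_energy ? wrap(trace) : R_NilValue);
}
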
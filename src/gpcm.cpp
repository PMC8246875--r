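#include <Rcpp.h>
using namespace Rcpp;

// Penalized joint GPCM objective (negated, for minimizers) and its gradient.
//
// Parameter vector layout: [theta (N, only if theta_free)] [beta, item-major,
// m_i entries per item] [log alpha (P)].  Responses X are 0-based category
// codes with NA for missing cells; m[i] is the top category of item i.
// The objective is
//   F = sum_cells log P(x | theta, beta, alpha)
//       - penalize_theta * lambda_theta * sum(theta^2)
//       - lambda_alpha * sum(log(alpha)^2)
// and the function returns (-F, -grad F) in the (theta, beta, log alpha)
// parameterization.  All category sums use max-subtraction so that large
// |alpha * (theta - beta)| cannot overflow.
// [[Rcpp::export]]
List gpcm_negobj(NumericVector par, IntegerMatrix X, IntegerVector m,
                 NumericVector theta_fixed, bool theta_free,
                 double lambda_theta, double lambda_alpha,
                 bool penalize_theta) {
  const int N = X.nrow(), P = X.ncol();
  std::vector<int> off(P + 1, 0);
  int maxm = 1;
  for (int i = 0; i < P; ++i) {
    off[i + 1] = off[i] + m[i];
    if (m[i] > maxm) maxm = m[i];
  }
  const int nb = off[P];
  const int ptheta = theta_free ? N : 0;
  if ((int)par.size() != ptheta + nb + P) stop("parameter vector has wrong length");
  if (!theta_free && theta_fixed.size() != N) stop("theta_fixed has wrong length");

  const double *th = theta_free ? &par[0] : &theta_fixed[0];
  const double *be = &par[ptheta];
  const double *la = &par[ptheta + nb];

  NumericVector grad(par.size());
  double *gth = theta_free ? &grad[0] : (double *)nullptr;
  double *gbe = &grad[ptheta];
  double *gla = &grad[ptheta + nb];

  std::vector<double> Bcum(maxm), T(maxm + 1), C(maxm + 1), p(maxm + 1);
  double F = 0.0;

  for (int i = 0; i < P; ++i) {
    const int mi = m[i];
    const double ai = std::exp(la[i]);
    double b = 0.0;
    for (int j = 0; j < mi; ++j) { b += be[off[i] + j]; Bcum[j] = b; }
    for (int n = 0; n < N; ++n) {
      const int x = X(n, i);
      if (x == NA_INTEGER) continue;
      const double t = th[n];
      T[0] = 0.0; C[0] = 0.0;
      double cmax = 0.0;
      for (int k = 1; k <= mi; ++k) {
        T[k] = k * t - Bcum[k - 1];
        C[k] = ai * T[k];
        if (C[k] > cmax) cmax = C[k];
      }
      double Z = 0.0;
      for (int k = 0; k <= mi; ++k) { p[k] = std::exp(C[k] - cmax); Z += p[k]; }
      const double logZ = std::log(Z) + cmax;
      for (int k = 0; k <= mi; ++k) p[k] /= Z;
      F += C[x] - logZ;
      double E = 0.0, ET = 0.0;
      for (int k = 1; k <= mi; ++k) { E += k * p[k]; ET += T[k] * p[k]; }
      if (theta_free) gth[n] += ai * (x - E);
      double tail = 0.0;  // P(X >= j), built from the top category down
      for (int j = mi; j >= 1; --j) {
        tail += p[j];
        gbe[off[i] + j - 1] += ai * (tail - (x >= j ? 1.0 : 0.0));
      }
      gla[i] += ai * (T[x] - ET);
    }
    F -= lambda_alpha * la[i] * la[i];
    gla[i] -= 2.0 * lambda_alpha * la[i];
  }
  if (theta_free && penalize_theta) {
    for (int n = 0; n < N; ++n) {
      F -= lambda_theta * th[n] * th[n];
      gth[n] -= 2.0 * lambda_theta * th[n];
    }
  }
  for (R_xlen_t k = 0; k < grad.size(); ++k) grad[k] = -grad[k];
  return List::create(_["value"] = -F, _["gradient"] = grad);
}
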
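#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Scaled forward-backward pass over a set of tracks for an HMM whose
// emissions are isotropic 2-D Gaussian displacements: the per-step
// emission log density under state k is
//   log b_k(t) = -log(2*pi) + elog_lam[k] - e_lam[k] * r2[t] / 2,
// with elog_lam = E[log lambda_k], e_lam = E[lambda_k] the variational
// moments of the state's step precision.  log_pi and log_A are the
// variational "tilde" parameters E[log pi] / E[log A]; the accumulated
// log normalizer is then the track-sum term of the evidence lower bound.
//
// Returns the expected per-state step counts N_k, the responsibility-
// weighted sums S_k = sum_t gamma_tk r2_t, expected transition counts xi
// (K x K), expected initial-state counts, the total log normalizer, and
// (only when want_gamma) the full responsibility matrix.
// [[Rcpp::export]]
List vb_forward_backward_cpp(NumericVector r2,
                             NumericVector elog_lam, NumericVector e_lam,
                             IntegerVector track_start,  // 0-based
                             IntegerVector track_len,
                             NumericVector log_pi,
                             NumericMatrix log_A,
                             bool want_gamma = false) {
  const int n = r2.size();
  const int K = elog_lam.size();
  const int ntr = track_start.size();
  const double LOG2PI = std::log(2.0 * M_PI);

  NumericMatrix xi(K, K);
  NumericVector init(K), N_k(K), S_k(K);
  NumericMatrix gamma(want_gamma ? n : 0, want_gamma ? K : 0);
  double loglik = 0.0;

  std::vector<double> A(K * K), piv(K);
  for (int k = 0; k < K; ++k) piv[k] = std::exp(log_pi[k]);
  for (int a = 0; a < K; ++a)
    for (int b = 0; b < K; ++b) A[a * K + b] = std::exp(log_A(a, b));

  std::vector<double> alpha, beta, B, cvec, g(K);
  for (int tr = 0; tr < ntr; ++tr) {
    const int s0 = track_start[tr], T = track_len[tr];
    if (T <= 0) continue;
    alpha.assign(T * K, 0.0);
    beta.assign(T * K, 0.0);
    B.assign(T * K, 0.0);
    cvec.assign(T, 0.0);

    // emission densities, rescaled per step for numerical stability
    for (int t = 0; t < T; ++t) {
      double m = -std::numeric_limits<double>::infinity();
      for (int k = 0; k < K; ++k) {
        double lb = -LOG2PI + elog_lam[k] - 0.5 * e_lam[k] * r2[s0 + t];
        B[t * K + k] = lb;
        if (lb > m) m = lb;
      }
      for (int k = 0; k < K; ++k) B[t * K + k] = std::exp(B[t * K + k] - m);
      loglik += m;  // restored through the scaling constants
    }

    // forward
    double c0 = 0.0;
    for (int k = 0; k < K; ++k) { alpha[k] = piv[k] * B[k]; c0 += alpha[k]; }
    if (c0 <= 0.0) stop("zero forward mass; emission underflow");
    for (int k = 0; k < K; ++k) alpha[k] /= c0;
    cvec[0] = c0;
    for (int t = 1; t < T; ++t) {
      double ct = 0.0;
      for (int k = 0; k < K; ++k) {
        double acc = 0.0;
        for (int j = 0; j < K; ++j) acc += alpha[(t - 1) * K + j] * A[j * K + k];
        alpha[t * K + k] = acc * B[t * K + k];
        ct += alpha[t * K + k];
      }
      if (ct <= 0.0) stop("zero forward mass; emission underflow");
      for (int k = 0; k < K; ++k) alpha[t * K + k] /= ct;
      cvec[t] = ct;
    }
    for (int t = 0; t < T; ++t) loglik += std::log(cvec[t]);

    // backward
    for (int k = 0; k < K; ++k) beta[(T - 1) * K + k] = 1.0;
    for (int t = T - 2; t >= 0; --t) {
      for (int k = 0; k < K; ++k) {
        double acc = 0.0;
        for (int j = 0; j < K; ++j)
          acc += A[k * K + j] * B[(t + 1) * K + j] * beta[(t + 1) * K + j];
        beta[t * K + k] = acc / cvec[t + 1];
      }
    }

    // responsibilities, sufficient statistics, transition counts
    for (int t = 0; t < T; ++t) {
      double norm = 0.0;
      for (int k = 0; k < K; ++k) {
        g[k] = alpha[t * K + k] * beta[t * K + k];
        norm += g[k];
      }
      for (int k = 0; k < K; ++k) {
        double gk = g[k] / norm;
        N_k[k] += gk;
        S_k[k] += gk * r2[s0 + t];
        if (want_gamma) gamma(s0 + t, k) = gk;
        if (t == 0) init[k] += gk;
      }
    }
    for (int t = 0; t < T - 1; ++t) {
      for (int a = 0; a < K; ++a) {
        double al = alpha[t * K + a];
        if (al == 0.0) continue;
        for (int b = 0; b < K; ++b)
          xi(a, b) += al * A[a * K + b] * B[(t + 1) * K + b] *
                      beta[(t + 1) * K + b] / cvec[t + 1];
      }
    }
  }

  List out = List::create(_["N_k"] = N_k, _["S_k"] = S_k, _["xi"] = xi,
                          _["init"] = init, _["loglik"] = loglik);
  if (want_gamma) out["gamma"] = gamma;
  return out;
}
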
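#include <Rcpp.h>
using namespace Rcpp;

// Forward (filtering) log-likelihood of colored photon sequences under a
// hidden continuous-time Markov chain. Bursts are concatenated; the first
// photon of each burst (gap_idx == 0) restarts the recursion at the initial
// distribution. Propagators for the interphoton intervals are precomputed on
// the R side (one K x K slice per unique clock-quantized interval) and
// indexed per photon by gap_idx (1-based). Emission: P(acceptor | state i) =
// E[i]. Per-photon normalization keeps the recursion stable for arbitrarily
// long bursts.

// [[Rcpp::export]]
double h2mm_loglik_cpp(const IntegerVector& colors,
                       const IntegerVector& gap_idx,
                       const NumericVector& P,
                       const NumericVector& E,
                       const NumericVector& pi0,
                       const int K) {
  const int n = colors.size();
  const double* Pp = REAL(P);
  std::vector<double> alpha(K), tmp(K);
  double ll = 0.0;
  for (int t = 0; t < n; ++t) {
    const int g = gap_idx[t];
    if (g == 0) {
      for (int i = 0; i < K; ++i) alpha[i] = pi0[i];
    } else {
      const double* M = Pp + (size_t)(g - 1) * K * K; // column-major K x K
      for (int j = 0; j < K; ++j) tmp[j] = 0.0;
      for (int i = 0; i < K; ++i) {
        const double a = alpha[i];
        if (a == 0.0) continue;
        for (int j = 0; j < K; ++j) tmp[j] += a * M[i + j * K];
      }
      for (int j = 0; j < K; ++j) alpha[j] = tmp[j];
    }
    const int c = colors[t];
    double s = 0.0;
    for (int i = 0; i < K; ++i) {
      alpha[i] *= (c == 1) ? E[i] : (1.0 - E[i]);
      s += alpha[i];
    }
    if (s <= 0.0) return R_NegInf;
    for (int i = 0; i < K; ++i) alpha[i] /= s;
    ll += std::log(s);
  }
  return ll;
}

// Most-likely hidden state path (Viterbi) under the same propagator and
// emission model, in log space. Returns 1-based states per photon.

// [[Rcpp::export]]
IntegerVector h2mm_viterbi_cpp(const IntegerVector& colors,
                               const IntegerVector& gap_idx,
                               const NumericVector& P,
                               const NumericVector& E,
                               const NumericVector& pi0,
                               const int K) {
  const int n = colors.size();
  const double* Pp = REAL(P);
  IntegerVector path(n);
  if (n == 0) return path;
  const double NEG = -std::numeric_limits<double>::infinity();
  std::vector<double> logE1(K), logE0(K), logpi(K);
  for (int i = 0; i < K; ++i) {
    logE1[i] = E[i] > 0 ? std::log(E[i]) : NEG;
    logE0[i] = E[i] < 1 ? std::log(1.0 - E[i]) : NEG;
    logpi[i] = pi0[i] > 0 ? std::log(pi0[i]) : NEG;
  }
  std::vector<double> delta(n * (size_t)K);
  std::vector<int> psi(n * (size_t)K);
  int burst_start = 0;
  auto backtrack = [&](int s, int e) {
    // argmax at e, then follow back-pointers to s
    int best = 0;
    for (int i = 1; i < K; ++i)
      if (delta[(size_t)e * K + i] > delta[(size_t)e * K + best]) best = i;
    for (int t = e; t >= s; --t) {
      path[t] = best + 1;
      if (t > s) best = psi[(size_t)t * K + best];
    }
  };
  for (int t = 0; t < n; ++t) {
    const int c = colors[t];
    if (gap_idx[t] == 0 && t > 0) { backtrack(burst_start, t - 1); burst_start = t; }
    if (gap_idx[t] == 0) {
      for (int i = 0; i < K; ++i)
        delta[(size_t)t * K + i] = logpi[i] + (c == 1 ? logE1[i] : logE0[i]);
    } else {
      const double* M = Pp + (size_t)(gap_idx[t] - 1) * K * K;
      for (int j = 0; j < K; ++j) {
        double best = NEG; int arg = 0;
        for (int i = 0; i < K; ++i) {
          const double m = M[i + j * K];
          const double v = (m > 0 ? delta[(size_t)(t - 1) * K + i] + std::log(m) : NEG);
          if (v > best) { best = v; arg = i; }
        }
        delta[(size_t)t * K + j] = best + (c == 1 ? logE1[j] : logE0[j]);
        psi[(size_t)t * K + j] = arg;
      }
    }
  }
  backtrack(burst_start, n - 1);
  return path;
}
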
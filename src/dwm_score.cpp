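#include <Rcpp.h>
using namespace Rcpp;

// Log-space scoring kernels for PWM / DWM window likelihoods.
// Conventions: base codes are 0..3 (A,C,G,T), -1 marks a non-ACGT
// position (windows containing one are skipped). logw is L x 4
// (positions x bases). logpairs has one row per ordered pair i < j in
// the enumeration (0,1),(0,2),...,(L-2,L-1); row entries are the 16
// log joint probabilities in row-major (base-at-i, base-at-j) order.

static inline double logsumexp4(const double* v) {
  double m = v[0];
  for (int a = 1; a < 4; ++a) if (v[a] > m) m = v[a];
  double s = 0.0;
  for (int a = 0; a < 4; ++a) s += std::exp(v[a] - m);
  return m + std::log(s);
}

static inline int pair_row(int i, int j, int L) {
  // 0-based i < j
  return i * L - i * (i + 1) / 2 + (j - i) - 1;
}

static inline double lp_pair(const NumericMatrix& lp, int i, int j,
                             int a, int b, int L) {
  // log pair(i, j)[a, b]; i > j resolved by the symmetry convention
  if (i < j) return lp(pair_row(i, j, L), a * 4 + b);
  return lp(pair_row(j, i, L), b * 4 + a);
}

// Posterior-likelihood score of one window under a DWM: for each
// position i the unnormalised posterior weight of base a is
//   u_i(a) = w_i(a) * prod_{j != i} pair(i,j)[a, s_j] / w_i(a)
// (all in log space), Z_i its log-sum over a, and the window
// log-likelihood is sum_i [log u_i(s_i) - log Z_i].
// [[Rcpp::export]]
List cpp_dwm_posterior(NumericMatrix logw, NumericMatrix logpairs,
                       IntegerVector codes) {
  const int L = logw.nrow();
  if (codes.size() != L) stop("window length does not match model length");
  NumericMatrix logu(4, L);
  NumericVector logz(L);
  double ll = 0.0;
  for (int i = 0; i < L; ++i) {
    double u[4];
    for (int a = 0; a < 4; ++a) {
      double v = logw(i, a);
      for (int j = 0; j < L; ++j) {
        if (j == i) continue;
        v += lp_pair(logpairs, i, j, a, codes[j], L) - logw(i, a);
      }
      u[a] = v;
      logu(a, i) = v;
    }
    const double z = logsumexp4(u);
    logz[i] = z;
    ll += u[codes[i]] - z;
  }
  return List::create(_["loglik"] = ll, _["logu"] = logu, _["logz"] = logz);
}

// Per-start log-odds of every window of a sequence against a
// background (single orientation). NA where the window contains a
// non-ACGT base. logpairs_ = R_NilValue scores with the PWM alone.
// [[Rcpp::export]]
NumericVector cpp_scan_logodds(NumericMatrix logw,
                               Nullable<NumericMatrix> logpairs_,
                               IntegerVector codes, NumericVector logbg) {
  const int L = logw.nrow();
  const int n = codes.size();
  if (n < L) return NumericVector(0);
  const int nw = n - L + 1;
  NumericVector out(nw, NA_REAL);
  const bool use_dwm = logpairs_.isNotNull();
  NumericMatrix logpairs;
  if (use_dwm) logpairs = logpairs_.get();

  // distance to next invalid base, for O(1) window validity checks
  std::vector<int> next_bad(n + 1);
  next_bad[n] = n;
  for (int p = n - 1; p >= 0; --p)
    next_bad[p] = (codes[p] < 0) ? p : next_bad[p + 1];

  for (int p = 0; p < nw; ++p) {
    if (next_bad[p] < p + L) continue;
    double ll = 0.0, bg = 0.0;
    if (!use_dwm) {
      for (int k = 0; k < L; ++k) ll += logw(k, codes[p + k]);
    } else {
      for (int i = 0; i < L; ++i) {
        double u[4];
        for (int a = 0; a < 4; ++a) {
          double v = logw(i, a);
          for (int j = 0; j < L; ++j) {
            if (j == i) continue;
            v += lp_pair(logpairs, i, j, a, codes[p + j], L) - logw(i, a);
          }
          u[a] = v;
        }
        ll += u[codes[p + i]] - logsumexp4(u);
      }
    }
    for (int k = 0; k < L; ++k) bg += logbg[codes[p + k]];
    out[p] = ll - bg;
  }
  return out;
}
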
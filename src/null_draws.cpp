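#include <Rcpp.h>
using namespace Rcpp;

// Permutation null SCC draws for pseudo-TADs of size L.
//
// For each of the N permutations and each off-diagonal d = 1..dmax,
// L - d positions are sampled uniformly without replacement from the
// n - d valid positions of that diagonal (partial Fisher-Yates driven by
// R's RNG, so draws are reproducible under set.seed).  Per diagonal the
// stratum Pearson moments are accumulated with both-zero pairs excluded;
// the SCC numerator contribution of a stratum is N_k * cov and the
// denominator contribution N_k * sd1 * sd2.  Strata with fewer than two
// retained pairs or zero variance get weight zero.  Undefined SCCs are
// returned as NA.
//
// The index pool is initialized once per diagonal and each permutation's
// swaps are undone afterwards, so the per-permutation cost is O(L - d)
// rather than O(n).  Note the diagonal loop is outermost: the RNG draw
// order therefore differs from assembling one pseudo-TAD at a time, but
// the sampled law is identical.
// [[Rcpp::export]]
NumericVector cpp_null_scc_draws(const NumericMatrix& M1,
                                 const NumericMatrix& M2,
                                 int L, int N, int dmax) {
  const int n = M1.nrow();
  const double* m1 = REAL(M1);
  const double* m2 = REAL(M2);
  std::vector<double> num(N, 0.0), den(N, 0.0);
  std::vector<int> idx(n), taken;
  for (int d = 1; d <= dmax; ++d) {
    const int m = L - d;
    const int avail = n - d;
    if (m < 1 || avail < m) break;
    for (int t = 0; t < avail; ++t) idx[t] = t;
    taken.assign(m, 0);
    for (int p = 0; p < N; ++p) {
      double s1 = 0, s2 = 0, s11 = 0, s22 = 0, s12 = 0;
      int nk = 0;
      if (m < avail) {
        for (int t = 0; t < m; ++t) {
          int r = t + (int)(unif_rand() * (avail - t));
          if (r >= avail) r = avail - 1;
          std::swap(idx[t], idx[r]);
          taken[t] = r;
        }
      }
      for (int t = 0; t < m; ++t) {
        const int i = idx[t];
        const double v1 = m1[i + (size_t)(i + d) * n];
        const double v2 = m2[i + (size_t)(i + d) * n];
        if (v1 == 0.0 && v2 == 0.0) continue;
        ++nk;
        s1 += v1; s2 += v2;
        s11 += v1 * v1; s22 += v2 * v2; s12 += v1 * v2;
      }
      if (m < avail) {           // restore the identity pool
        for (int t = m - 1; t >= 0; --t) std::swap(idx[t], idx[taken[t]]);
      }
      if (nk < 2) continue;
      const double cv = (s12 - s1 * s2 / nk) / (nk - 1);
      double v1v = (s11 - s1 * s1 / nk) / (nk - 1);
      double v2v = (s22 - s2 * s2 / nk) / (nk - 1);
      if (v1v <= 0.0 || v2v <= 0.0) continue;
      num[p] += nk * cv;
      den[p] += nk * std::sqrt(v1v) * std::sqrt(v2v);
    }
  }
  NumericVector out(N);
  for (int p = 0; p < N; ++p) {
    if (den[p] > 0.0) {
      double rho = num[p] / den[p];
      if (rho > 1.0) rho = 1.0;
      if (rho < -1.0) rho = -1.0;
      out[p] = rho;
    } else {
      out[p] = NA_REAL;
    }
  }
  return out;
}
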
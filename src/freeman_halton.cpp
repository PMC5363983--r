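#include <Rcpp.h>
using namespace Rcpp;

// Exact Freeman-Halton test for an r x 2 contingency table by complete
// enumeration of all tables sharing the observed margins.
//
// The two-sided p-value sums the multivariate hypergeometric
// probabilities of every table whose probability does not exceed that
// of the observed table (relative tie tolerance `tol`).
//
// Returns p, the total enumerated probability (== 1 up to rounding,
// a completeness check) and the number of enumerated tables.
// [[Rcpp::export(name = ".freemanHaltonCpp")]]
List freeman_halton_cpp(IntegerMatrix tab, double tol = 1e-7,
                        double guard = 1e7) {
  const int r = tab.nrow();
  if (tab.ncol() != 2) stop("table must have exactly 2 columns");
  if (r < 2) stop("table must have at least 2 rows");

  std::vector<double> n(r);
  double A = 0.0, N = 0.0;
  for (int i = 0; i < r; i++) {
    if (tab(i, 0) < 0 || tab(i, 1) < 0) stop("counts must be non-negative");
    n[i] = tab(i, 0) + tab(i, 1);
    A += tab(i, 0);
    N += n[i];
  }

  // count margin-compatible tables by dynamic programming; enforce guard
  {
    std::vector<double> cnt((size_t)A + 1, 0.0);
    cnt[0] = 1.0;
    for (int i = 0; i < r; i++) {
      std::vector<double> nxt((size_t)A + 1, 0.0);
      for (int a = 0; a <= (int)A; a++) {
        if (cnt[a] == 0) continue;
        int kmax = std::min((int)n[i], (int)A - a);
        for (int kk = 0; kk <= kmax; kk++) nxt[a + kk] += cnt[a];
      }
      cnt.swap(nxt);
    }
    if (cnt[(size_t)A] > guard)
      stop("enumeration guard exceeded: %.3g candidate tables", cnt[(size_t)A]);
  }

  const double lden = R::lchoose(N, A);
  double lp_obs = -lden;
  for (int i = 0; i < r; i++) lp_obs += R::lchoose(n[i], tab(i, 0));
  const double thresh = lp_obs + log1p(tol);

  // per-row lchoose lookup
  std::vector< std::vector<double> > lc(r);
  for (int i = 0; i < r; i++) {
    int ni = (int)n[i];
    lc[i].resize(ni + 1);
    for (int kk = 0; kk <= ni; kk++) lc[i][kk] = R::lchoose(n[i], kk);
  }

  double psum = 0.0, total = 0.0, ntab = 0.0;
  std::vector<int> kcur(r, -1);
  std::vector<double> rem(r + 1), lp(r + 1);
  rem[0] = A;
  lp[0] = -lden;
  int i = 0;
  while (i >= 0) {
    if (i == r - 1) {
      int kk = (int)rem[i];
      if (kk >= 0 && kk <= (int)n[i]) {
        double lpt = lp[i] + lc[i][kk];
        double p = exp(lpt);
        total += p;
        ntab += 1.0;
        if (lpt <= thresh) psum += p;
      }
      i--;
      continue;
    }
    kcur[i]++;
    int kmax = std::min((int)n[i], (int)rem[i]);
    if (kcur[i] > kmax) {
      kcur[i] = -1;
      i--;
      continue;
    }
    rem[i + 1] = rem[i] - kcur[i];
    lp[i + 1] = lp[i] + lc[i][kcur[i]];
    i++;
  }

  return List::create(_["p"] = std::min(psum, 1.0),
                      _["total"] = total,
                      _["n_tables"] = ntab);
}
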
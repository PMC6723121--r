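#include <Rcpp.h>
using namespace Rcpp;

// Inbreeding coefficients by the Meuwissen & Luo (1992) recursion on the
// A = T D T' decomposition. Pedigree must be sorted parents-before-offspring;
// sire/dam are 1-based ids, 0 = unknown. Returns F and the Mendelian-sampling
// variances d (diagonal of D), so that |A| = prod(d).
// [[Rcpp::export]]
List cpp_inbreeding(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericVector F(n), d(n);
  std::vector<double> L(n, 0.0);
  for (int i = 0; i < n; ++i) {
    int s = sire[i], m = dam[i];
    if (s > i || m > i)
      stop("pedigree not sorted: parent id not smaller than offspring id");
    if (s == 0 && m == 0)      d[i] = 1.0;
    else if (s == 0)           d[i] = 0.75 - 0.25 * F[m - 1];
    else if (m == 0)           d[i] = 0.75 - 0.25 * F[s - 1];
    else                       d[i] = 0.5 - 0.25 * (F[s - 1] + F[m - 1]);
    if (s == 0 || m == 0) { F[i] = 0.0; continue; }
    // a_ii = sum over ancestors j of L_j^2 d_j, accumulating L down the pedigree
    std::fill(L.begin(), L.begin() + i + 1, 0.0);
    L[i] = 1.0;
    double aii = 0.0;
    for (int j = i; j >= 0; --j) {
      double lj = L[j];
      if (lj == 0.0) continue;
      aii += lj * lj * d[j];
      int js = sire[j], jm = dam[j];
      if (js > 0) L[js - 1] += 0.5 * lj;
      if (jm > 0) L[jm - 1] += 0.5 * lj;
    }
    F[i] = aii - 1.0;
  }
  return List::create(_["F"] = F, _["d"] = d);
}
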
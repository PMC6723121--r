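#include <Rcpp.h>
using namespace Rcpp;

// Selected inversion of a symmetric matrix from its simplicial LDL' factor
// (CHOLMOD storage: per column, D on the diagonal entry followed by the
// unit-L off-diagonals, rows sorted). The inverse is computed on the full
// symmetric pattern of L + L' by the Takahashi equations
//   Z_ij = delta_ij / d_i - sum_{k > i, L_ki != 0} L_ki Z_kj ,  i <= j,
// processing columns j = n..1 and rows descending within a column; entries
// below the diagonal are mirror copies of already-computed columns. The
// Cholesky fill pattern is closed under the recursion (Erisman & Tinney),
// so every referenced entry lies on the pattern.

// Symbolic analysis: build the full (both-triangle) pattern of L + L' in
// CSC form plus, for every below-diagonal entry, the position of its mirror.
// Reused across REML iterations since the factor pattern is fixed.
// [[Rcpp::export]]
List cpp_takahashi_analyze(IntegerVector Lp, IntegerVector Li, int n) {
  const int *p = INTEGER(Lp), *ri = INTEGER(Li);
  int nnz_low = Lp[n];
  // column counts of the full pattern: lower part + transposed strict lower
  std::vector<int> cnt(n, 0);
  for (int c = 0; c < n; ++c) {
    cnt[c] += p[c + 1] - p[c];
    for (int q = p[c] + 1; q < p[c + 1]; ++q) cnt[ri[q]] += 1;
  }
  IntegerVector Zp(n + 1);
  for (int c = 0; c < n; ++c) Zp[c + 1] = Zp[c] + cnt[c];
  int nnz_full = Zp[n];
  IntegerVector Zi(nnz_full);
  IntegerVector mirror(nnz_full, -1);
  std::vector<int> head(n);
  for (int c = 0; c < n; ++c) head[c] = Zp[c];
  // upper entries: transpose of the strict lower part, ascending column
  // order keeps rows sorted; remember where each lower entry's mirror went
  std::vector<int> up_of_low(nnz_low, -1);
  for (int c = 0; c < n; ++c)
    for (int q = p[c] + 1; q < p[c + 1]; ++q) {
      int r = ri[q];           // lower entry (r, c), r > c
      int fp = head[r]++;      // upper slot (c, r) in column r
      Zi[fp] = c;
      up_of_low[q] = fp;
    }
  // diagonal + below-diagonal entries, straight from the lower pattern
  for (int c = 0; c < n; ++c)
    for (int q = p[c]; q < p[c + 1]; ++q) {
      int fp = head[c]++;
      Zi[fp] = ri[q];
      if (ri[q] > c) mirror[fp] = up_of_low[q];
    }
  return List::create(_["Zp"] = Zp, _["Zi"] = Zi, _["mirror"] = mirror);
}

// Numeric phase: inverse entries on the full pattern.
// [[Rcpp::export]]
NumericVector cpp_takahashi(IntegerVector Lp, IntegerVector Li,
                            NumericVector Lx, int n, IntegerVector Zp,
                            IntegerVector Zi, IntegerVector mirror) {
  const int *p = INTEGER(Lp), *ri = INTEGER(Li);
  const double *lx = REAL(Lx);
  const int *zp = INTEGER(Zp), *zi = INTEGER(Zi), *mir = INTEGER(mirror);
  NumericVector Zx(Zp[n]);
  double *zx = REAL(Zx);
  std::vector<double> work(n, 0.0);
  for (int j = n - 1; j >= 0; --j) {
    int q0 = zp[j], q1 = zp[j + 1];
    // reverse sweep: below-diagonal rows first (mirror copies), then the
    // diagonal and upper rows via the recursion, all scattered into work
    for (int q = q1 - 1; q >= q0; --q) {
      int i = zi[q];
      double v;
      if (i > j) {
        v = zx[mir[q]];
      } else {
        v = (i == j) ? 1.0 / lx[p[i]] : 0.0;
        for (int t = p[i] + 1; t < p[i + 1]; ++t)
          v -= lx[t] * work[ri[t]];
      }
      zx[q] = v;
      work[i] = v;
    }
    for (int q = q0; q < q1; ++q) work[zi[q]] = 0.0;
  }
  return Zx;
}

// 1-based positions of entries (r, c) (0-based permuted indices) in the
// full pattern; 0 when absent.
// [[Rcpp::export]]
IntegerVector cpp_full_positions(IntegerVector Zp, IntegerVector Zi,
                                 IntegerVector r, IntegerVector c) {
  int m = r.size();
  IntegerVector out(m);
  const int *p = INTEGER(Zp), *ri = INTEGER(Zi);
  for (int t = 0; t < m; ++t) {
    int col = c[t], row = r[t];
    int lo = p[col], hi = p[col + 1] - 1, pos = 0;
    while (lo <= hi) {
      int mid = (lo + hi) / 2;
      if (ri[mid] == row) { pos = mid + 1; break; }
      if (ri[mid] < row) lo = mid + 1; else hi = mid - 1;
    }
    out[t] = pos;
  }
  return out;
}
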
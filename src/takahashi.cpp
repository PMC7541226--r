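#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Selected inverse (Takahashi equations) of a sparse SPD matrix from its
// simplicial Cholesky factor A = L L' (L lower triangular, CSC, row
// indices sorted ascending within each column, diagonal entry first).
// Returns the values of Z = A^{-1} on the pattern of L.
//
// For column j with row set S_j, the recursion is
//   Z_ij = (delta_ij / L_jj - sum_{k in S_j, k > j} L_kj Z_ik) / L_jj.
// The pattern of a Cholesky factor is closed (i, k in S_j, i >= k > j
// implies L_ik != 0), so every needed Z entry lies inside the already
// computed columns; the pair sums are accumulated by scanning each
// column k once against a dense membership mask, which keeps the cost at
// sum_k |col_k| * |row_k| sequential operations.
// [[Rcpp::export]]
NumericVector takahashi_selected_inverse(IntegerVector Lp, IntegerVector Li,
                                         NumericVector Lx) {
  const int m = Lp.size() - 1;
  NumericVector Zx(Lx.size());
  std::vector<char> inS(m, 0);      // membership of a row in S_j
  std::vector<double> wL(m, 0.0);   // scattered L values of column j
  std::vector<double> s(m, 0.0);    // accumulators s_i for column j
  for (int j = m - 1; j >= 0; --j) {
    const int cst = Lp[j], cen = Lp[j + 1];
    if (cst >= cen) continue;
    const double ljj = Lx[cst];     // diagonal first (sorted rows)
    for (int t = cst; t < cen; ++t) {
      const int i = Li[t];
      inS[i] = 1; wL[i] = Lx[t]; s[i] = 0.0;
    }
    // accumulate s_i = sum_k L_kj Z_ik over unordered pairs {i, k} in
    // S_j \ {j}: the entry for pair (b >= a) sits in column a
    for (int t = cst + 1; t < cen; ++t) {
      const int k = Li[t];
      const double lkj = Lx[t];
      for (int u = Lp[k]; u < Lp[k + 1]; ++u) {
        const int i = Li[u];
        if (!inS[i]) continue;
        const double z = Zx[u];          // Z_ik with i >= k
        s[i] += lkj * z;
        if (i != k) s[k] += wL[i] * z;
      }
    }
    for (int t = cen - 1; t > cst; --t)
      Zx[t] = -s[Li[t]] / ljj;
    // diagonal: uses the freshly computed off-diagonals of column j
    double sj = 0.0;
    for (int t = cst + 1; t < cen; ++t) sj += Lx[t] * Zx[t];
    Zx[cst] = (1.0 / ljj - sj) / ljj;
    for (int t = cst; t < cen; ++t) inS[Li[t]] = 0;
  }
  return Zx;
}

// Numerator relationship matrix by the tabular method.  si/di are 1-based
// indices of sire and dam (0 = unknown) in a parents-first ordering.
// [[Rcpp::export]]
NumericMatrix tabular_a(IntegerVector si, IntegerVector di) {
  const int n = si.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    const int s = si[i] - 1, d = di[i] - 1;
    for (int j = 0; j < i; ++j) {
      double v = 0.0;
      if (s >= 0) v += 0.5 * A(j, s);
      if (d >= 0) v += 0.5 * A(j, d);
      A(j, i) = v;
      A(i, j) = v;
    }
    A(i, i) = 1.0 + ((s >= 0 && d >= 0) ? 0.5 * A(s, d) : 0.0);
  }
  return A;
}
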
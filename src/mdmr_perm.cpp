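#include <Rcpp.h>
using namespace Rcpp;

// Permutation statistics for one model term under the Freedman-Lane scheme.
//
// The permuted Gower matrix is G* = M G M' with M = Hr + P (I - Hr), P the
// permutation matrix. Writing A0 = Hr G Hr, E = (I-Hr) G (I-Hr) and
// C1 = Hr G (I-Hr), we have G* = A0 + P E P' + C1 P' + P C1', so any trace
// tr(S G*) with symmetric S reduces to O(n^2) gathers:
//   tr(S G*) = tr(S A0) + sum_ij S_ij E[p_i, p_j] + 2 sum_ij S_ij C1[i, p_j].
// Returns a B x 2 matrix: column 0 is the term numerator tr((Hf - Hr) G*),
// column 1 the residual trace tr((I - Hf) G*).
// [[Rcpp::export]]
NumericMatrix fl_perm_traces(NumericMatrix S1, NumericMatrix Hf,
                             NumericMatrix A0, NumericMatrix E,
                             NumericMatrix C1, IntegerMatrix perms) {
  const int n = S1.nrow(), B = perms.ncol();
  double s1A0 = 0.0, hfA0 = 0.0, trA0 = 0.0, trE = 0.0;
  for (int j = 0; j < n; ++j) {
    trA0 += A0(j, j);
    trE += E(j, j);
    for (int i = 0; i < n; ++i) {
      s1A0 += S1(i, j) * A0(i, j);
      hfA0 += Hf(i, j) * A0(i, j);
    }
  }
  NumericMatrix out(B, 2);
  for (int b = 0; b < B; ++b) {
    const int *p = &perms(0, b);
    double s1E = 0.0, hfE = 0.0, s1C = 0.0, hfC = 0.0, trC = 0.0;
    for (int j = 0; j < n; ++j) {
      const int pj = p[j];
      trC += C1(j, pj);
      const double *ecol = &E(0, 0) + (size_t)pj * n;
      const double *ccol = &C1(0, 0) + (size_t)pj * n;
      const double *s1col = &S1(0, 0) + (size_t)j * n;
      const double *hfcol = &Hf(0, 0) + (size_t)j * n;
      for (int i = 0; i < n; ++i) {
        const double e = ecol[p[i]];
        const double c = ccol[i];
        s1E += s1col[i] * e;
        hfE += hfcol[i] * e;
        s1C += s1col[i] * c;
        hfC += hfcol[i] * c;
      }
    }
    const double numer = s1A0 + s1E + 2.0 * s1C;
    const double trHfG = hfA0 + hfE + 2.0 * hfC;
    const double trG = trA0 + trE + 2.0 * trC;
    out(b, 0) = numer;
    out(b, 1) = trG - trHfG;
  }
  return out;
}

// Raw-label permutation scheme: G* = P G P'.
// Returns B x 2: term numerator and residual trace.
// [[Rcpp::export]]
NumericMatrix raw_perm_traces(NumericMatrix S1, NumericMatrix Hf,
                              NumericMatrix G, IntegerMatrix perms) {
  const int n = S1.nrow(), B = perms.ncol();
  double trG = 0.0;
  for (int j = 0; j < n; ++j) trG += G(j, j);
  NumericMatrix out(B, 2);
  for (int b = 0; b < B; ++b) {
    const int *p = &perms(0, b);
    double s1G = 0.0, hfG = 0.0;
    for (int j = 0; j < n; ++j) {
      const double *gcol = &G(0, 0) + (size_t)p[j] * n;
      const double *s1col = &S1(0, 0) + (size_t)j * n;
      const double *hfcol = &Hf(0, 0) + (size_t)j * n;
      for (int i = 0; i < n; ++i) {
        const double g = gcol[p[i]];
        s1G += s1col[i] * g;
        hfG += hfcol[i] * g;
      }
    }
    out(b, 0) = s1G;
    out(b, 1) = trG - hfG;
  }
  return out;
}

// Jack-knife effect-size kernel: pseudo-R2 increment of one term after
// shuffling a single outcome column.
//
// base holds the distance matrix D (manhattan) or squared distances D^2
// (euclidean); comp holds the column's additive component (|y_i - y_q| or
// (y_i - y_q)^2). After shuffling the column by p, the permuted distance
// entry is v = base_ij - comp_ij + comp[p_i, p_j], and A*_ij = -v^2/2
// (manhattan) or -v/2 (euclidean). With M1 = C (Hf - Hr) C and M2 = C (the
// centering matrix), the increment is sum(M1 * A*) / sum(M2 * A*).
// [[Rcpp::export]]
NumericVector jk_perm_r2(NumericMatrix base, NumericMatrix comp,
                         NumericMatrix M1, NumericMatrix M2,
                         IntegerMatrix perms, bool manhattan) {
  const int n = base.nrow(), K = perms.ncol();
  NumericVector out(K);
  for (int k = 0; k < K; ++k) {
    const int *p = &perms(0, k);
    double num = 0.0, den = 0.0;
    for (int j = 0; j < n; ++j) {
      const int pj = p[j];
      const double *bcol = &base(0, 0) + (size_t)j * n;
      const double *ccol = &comp(0, 0) + (size_t)j * n;
      const double *cpcol = &comp(0, 0) + (size_t)pj * n;
      const double *m1col = &M1(0, 0) + (size_t)j * n;
      const double *m2col = &M2(0, 0) + (size_t)j * n;
      for (int i = 0; i < n; ++i) {
        double v = bcol[i] - ccol[i] + cpcol[p[i]];
        double a = manhattan ? (-0.5 * v * v) : (-0.5 * v);
        num += m1col[i] * a;
        den += m2col[i] * a;
      }
    }
    out[k] = num / den;
  }
  return out;
}
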
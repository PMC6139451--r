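#include <Rcpp.h>
using namespace Rcpp;

// Rows of the lagged design for arbitrary window-end frames: row i is the
// bars-by-nLags window ending at frame sampleFrames[i], flattened
// column-major (bars fastest).
// [[Rcpp::export]]
NumericMatrix laggedRowsCpp(NumericMatrix S, int nLags,
                            IntegerVector sampleFrames) {
  const int nb = S.nrow();
  const int n = sampleFrames.size();
  NumericMatrix X(n, nb * nLags);
  for (int t = 0; t < nLags; ++t) {
    for (int i = 0; i < n; ++i) {
      const int f = sampleFrames[i] - nLags + t;  // 0-based column of S
      const double* src = &S(0, f);
      for (int b = 0; b < nb; ++b) X(i, t * nb + b) = src[b];
    }
  }
  return X;
}

// Context-field design rows: column k (cell (r, c) of the field, column-
// major) holds sum over assigned RF elements j of w_j * x_ij * xtilde_ijk,
// with xtilde the stimulus patch whose origin cell sits on element j.
// Wl is the RF reshaped bars-by-lags with non-assigned entries zeroed.
// Out-of-bounds stimulus cells contribute zero (zero padding).
// [[Rcpp::export]]
NumericMatrix cfRowsCpp(NumericMatrix S, NumericMatrix Wl,
                        IntegerVector sampleFrames, int height, int width,
                        int originRow, int originCol) {
  const int nb = S.nrow();
  const int nf = S.ncol();
  const int nl = Wl.ncol();
  const int n = sampleFrames.size();
  const int nk = height * width;
  NumericMatrix A(n, nk);
  std::vector<int> drs(nk), dcs(nk);
  for (int k = 0; k < nk; ++k) {
    drs[k] = (k % height) - (originRow - 1);
    dcs[k] = (k / height) - (originCol - 1);
  }
  std::vector<double> acc(nk);
  for (int i = 0; i < n; ++i) {
    const int base = sampleFrames[i] - nl;  // 0-based start frame
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int t = 0; t < nl; ++t) {
      const int f = base + t;
      const double* s = &S(0, f);
      for (int b = 0; b < nb; ++b) {
        const double v = Wl(b, t) * s[b];
        if (v == 0.0) continue;
        for (int k = 0; k < nk; ++k) {
          const int bb = b + drs[k];
          const int ff = f + dcs[k];
          if (bb < 0 || bb >= nb || ff < 0 || ff >= nf) continue;
          acc[k] += v * S(bb, ff);
        }
      }
    }
    for (int k = 0; k < nk; ++k) A(i, k) = acc[k];
  }
  return A;
}
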
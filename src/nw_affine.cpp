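#include <Rcpp.h>
using namespace Rcpp;

// Global affine-gap alignment (three-state Gotoh) over a precomputed matrix
// of column-pair scores. cs(i,j) is the score of pairing column i of profile
// A with column j of profile B (1-based in the DP, 0-based in cs). A gap of
// length L costs gap_open + L * gap_extend.
//
// Tie-breaking (fixed so output is bit-reproducible): at every choice the
// preference is diagonal (M) > vertical (gap in B, consume A) > horizontal
// (gap in A, consume B); on open-vs-extend ties within a gap state the
// extension is preferred.
//
// Returns a_cols / b_cols: for each aligned column the 1-based source column
// of A (resp. B) or NA for a gap.
// [[Rcpp::export]]
List nw_affine_path(NumericMatrix cs, double gap_open, double gap_extend) {
  const int la = cs.nrow(), lb = cs.ncol();
  const double NEG = -1e300;
  // state 0 = M (diagonal), 1 = X (gap in B, consume A), 2 = Y (gap in A)
  std::vector<double> M((la + 1) * (lb + 1), NEG);
  std::vector<double> X((la + 1) * (lb + 1), NEG);
  std::vector<double> Y((la + 1) * (lb + 1), NEG);
  // predecessor state for traceback, one byte per cell per state
  std::vector<unsigned char> pM((la + 1) * (lb + 1), 0);
  std::vector<unsigned char> pX((la + 1) * (lb + 1), 0);
  std::vector<unsigned char> pY((la + 1) * (lb + 1), 0);
  const int W = lb + 1;
#define AT(v, i, j) v[(i) * W + (j)]

  AT(M, 0, 0) = 0.0;
  for (int i = 1; i <= la; ++i) {
    AT(X, i, 0) = gap_open + i * gap_extend;
    AT(pX, i, 0) = 1;  // extend
  }
  for (int j = 1; j <= lb; ++j) {
    AT(Y, 0, j) = gap_open + j * gap_extend;
    AT(pY, 0, j) = 2;
  }
  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      // M: best predecessor diag cell over states, preference M > X > Y
      double m0 = AT(M, i - 1, j - 1), x0 = AT(X, i - 1, j - 1),
             y0 = AT(Y, i - 1, j - 1);
      double best = m0; unsigned char st = 0;
      if (x0 > best) { best = x0; st = 1; }
      if (y0 > best) { best = y0; st = 2; }
      AT(M, i, j) = best + cs(i - 1, j - 1);
      AT(pM, i, j) = st;
      // X: consume A column i (gap in B); extend preferred on tie
      double ext = AT(X, i - 1, j) + gap_extend;
      double opn_m = AT(M, i - 1, j) + gap_open + gap_extend;
      double opn_y = AT(Y, i - 1, j) + gap_open + gap_extend;
      best = ext; st = 1;
      if (opn_m > best) { best = opn_m; st = 0; }
      if (opn_y > best) { best = opn_y; st = 2; }
      AT(X, i, j) = best;
      AT(pX, i, j) = st;
      // Y: consume B column j (gap in A)
      ext = AT(Y, i, j - 1) + gap_extend;
      opn_m = AT(M, i, j - 1) + gap_open + gap_extend;
      double opn_x = AT(X, i, j - 1) + gap_open + gap_extend;
      best = ext; st = 2;
      if (opn_x > best) { best = opn_x; st = 1; }
      if (opn_m > best) { best = opn_m; st = 0; }
      AT(Y, i, j) = best;
      AT(pY, i, j) = st;
    }
  }
  double score = AT(M, la, lb); unsigned char state = 0;
  if (AT(X, la, lb) > score) { score = AT(X, la, lb); state = 1; }
  if (AT(Y, la, lb) > score) { score = AT(Y, la, lb); state = 2; }

  std::vector<int> acols, bcols;
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    if (state == 0) {
      unsigned char prev = AT(pM, i, j);
      acols.push_back(i); bcols.push_back(j);
      --i; --j; state = prev;
    } else if (state == 1) {
      unsigned char prev = AT(pX, i, j);
      acols.push_back(i); bcols.push_back(NA_INTEGER);
      --i; state = prev;
    } else {
      unsigned char prev = AT(pY, i, j);
      acols.push_back(NA_INTEGER); bcols.push_back(j);
      --j; state = prev;
    }
  }
  std::reverse(acols.begin(), acols.end());
  std::reverse(bcols.begin(), bcols.end());
#undef AT
  return List::create(_["score"] = score,
                      _["a_cols"] = IntegerVector(acols.begin(), acols.end()),
                      _["b_cols"] = IntegerVector(bcols.begin(), bcols.end()));
}
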
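#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap dynamic programming over a precomputed cell-score matrix.
//
// S[i, j] is the score of aligning position i of sequence/profile A against
// position j of B (1-based rows/cols correspond to residues; the DP adds a
// leading boundary row/column). A gap of length L scores
// gapOpen + (L - 1) * gapExtend, with gapOpen <= gapExtend < 0.
//
// States: M (A vs B), X (gap in A, consumes B), Y (gap in B, consumes A).
// Ties are broken M > X > Y in both state maxima and traceback, which makes
// the traceback deterministic (prefer substitution, then gap in the A row,
// then gap in the B row).
//
// mode: 0 = global (Needleman-Wunsch / Gotoh), 1 = local (Smith-Waterman).
//
// Returns list(score, ops, a0, b0) where ops is a string over {M, X, Y}
// read left-to-right along the alignment, and a0/b0 are the 0-based offsets
// of the first aligned position in A and B (always 0 for global).

static const double NEG_INF = -1e18;

// [[Rcpp::export(name = ".affineDP")]]
List affineDP(NumericMatrix S, double gapOpen, double gapExtend, int mode) {
  const int n = S.nrow(), m = S.ncol();
  const bool local = (mode == 1);

  // DP matrices, (n+1) x (m+1)
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> X((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Y((n + 1) * (m + 1), NEG_INF);
  // traceback: which predecessor state fed each cell (0=M,1=X,2=Y,3=start)
  std::vector<unsigned char> tbM((n + 1) * (m + 1), 3);
  std::vector<unsigned char> tbX((n + 1) * (m + 1), 3);
  std::vector<unsigned char> tbY((n + 1) * (m + 1), 3);

  const int W = m + 1;
#define IDX(i, j) ((i) * W + (j))

  M[IDX(0, 0)] = 0.0;
  if (!local) {
    for (int j = 1; j <= m; ++j) {
      X[IDX(0, j)] = gapOpen + (j - 1) * gapExtend;
      tbX[IDX(0, j)] = (j == 1) ? 0 : 1;
    }
    for (int i = 1; i <= n; ++i) {
      Y[IDX(i, 0)] = gapOpen + (i - 1) * gapExtend;
      tbY[IDX(i, 0)] = (i == 1) ? 0 : 2;
    }
  } else {
    for (int j = 1; j <= m; ++j) M[IDX(0, j)] = 0.0;
    for (int i = 1; i <= n; ++i) M[IDX(i, 0)] = 0.0;
  }

  double best = 0.0;
  int bi = 0, bj = 0;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = IDX(i, j), d = IDX(i - 1, j - 1);
      const int up = IDX(i - 1, j), lf = IDX(i, j - 1);

      // M: substitution, from best of M/X/Y at (i-1, j-1)
      double vm = M[d], vx = X[d], vy = Y[d];
      unsigned char arg = 0;
      double v = vm;
      if (vx > v) { v = vx; arg = 1; }
      if (vy > v) { v = vy; arg = 2; }
      double sub = (v <= NEG_INF / 2) ? NEG_INF : v + S(i - 1, j - 1);
      if (local && sub < 0.0) { sub = 0.0; arg = 3; }
      M[c] = sub;
      tbM[c] = arg;

      // X: gap in A (consume B[j])
      double xo_m = (M[lf] <= NEG_INF / 2) ? NEG_INF : M[lf] + gapOpen;
      double xo_x = (X[lf] <= NEG_INF / 2) ? NEG_INF : X[lf] + gapExtend;
      double xo_y = (Y[lf] <= NEG_INF / 2) ? NEG_INF : Y[lf] + gapOpen;
      v = xo_m; arg = 0;
      if (xo_x > v) { v = xo_x; arg = 1; }
      if (xo_y > v) { v = xo_y; arg = 2; }
      X[c] = v; tbX[c] = arg;

      // Y: gap in B (consume A[i])
      double yo_m = (M[up] <= NEG_INF / 2) ? NEG_INF : M[up] + gapOpen;
      double yo_x = (X[up] <= NEG_INF / 2) ? NEG_INF : X[up] + gapOpen;
      double yo_y = (Y[up] <= NEG_INF / 2) ? NEG_INF : Y[up] + gapExtend;
      v = yo_m; arg = 0;
      if (yo_x > v) { v = yo_x; arg = 1; }
      if (yo_y > v) { v = yo_y; arg = 2; }
      Y[c] = v; tbY[c] = arg;

      if (local && M[c] > best) { best = M[c]; bi = i; bj = j; }
    }
  }

  int i, j;
  unsigned char state; // 0=M,1=X,2=Y
  double score;
  if (local) {
    i = bi; j = bj; state = 0; score = best;
    if (bi == 0 && bj == 0) { // empty local alignment
      return List::create(_["score"] = 0.0, _["ops"] = "",
                          _["a0"] = 0, _["b0"] = 0);
    }
  } else {
    const int c = IDX(n, m);
    score = M[c]; state = 0;
    if (X[c] > score) { score = X[c]; state = 1; }
    if (Y[c] > score) { score = Y[c]; state = 2; }
    i = n; j = m;
  }

  std::string ops;
  while (i > 0 || j > 0) {
    unsigned char prev;
    if (state == 0) {
      // local alignments start at the first zero-scoring M cell
      if (local && M[IDX(i, j)] <= 0.0) break;
      prev = tbM[IDX(i, j)];
      ops.push_back('M');
      --i; --j;
    } else if (state == 1) {
      prev = tbX[IDX(i, j)];
      ops.push_back('X');
      --j;
    } else {
      prev = tbY[IDX(i, j)];
      ops.push_back('Y');
      --i;
    }
    if (prev == 3) break;
    state = prev;
  }
  std::reverse(ops.begin(), ops.end());

  return List::create(_["score"] = score, _["ops"] = ops,
                      _["a0"] = i, _["b0"] = j);
#undef IDX
}
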
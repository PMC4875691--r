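#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Affine-gap pairwise alignment by dynamic programming.
//
// Sequences arrive as 0-based integer state indices into `sub`.
// A gap of length L costs gap_open + L * gap_ext (opening the first gapped
// column pays both penalties), matching the usual pairwise-alignment
// convention so independent implementations agree cell for cell.
//
// local = true  -> Smith-Waterman (score floored at 0, best cell anywhere)
// local = false -> Needleman-Wunsch over the full sequences
//
// Returns raw score, 0-based half-open coordinates of the aligned segments,
// and (unless score_only) the aligned index paths with -1 marking gaps.

static const double NEG = -1e30;

// [[Rcpp::export]]
List pair_align_cpp(IntegerVector q, IntegerVector s, NumericMatrix sub,
                    double gap_open, double gap_ext,
                    bool local, bool score_only) {
  const int n = q.size(), m = s.size();
  const double go = gap_open + gap_ext, ge = gap_ext;

  std::vector<double> M(m + 1), X(m + 1), Y(m + 1);
  std::vector<double> Mp(m + 1), Xp(m + 1), Yp(m + 1);

  // traceback codes: 0 = stop/start, 1 = from M, 2 = from X, 3 = from Y
  std::vector<unsigned char> tbM, tbX, tbY;
  const bool tb = !score_only;
  if (tb) {
    tbM.assign((size_t)(n + 1) * (m + 1), 0);
    tbX.assign((size_t)(n + 1) * (m + 1), 0);
    tbY.assign((size_t)(n + 1) * (m + 1), 0);
  }
  const size_t W = (size_t)m + 1;

  for (int j = 0; j <= m; ++j) {
    Mp[j] = local ? (j == 0 ? 0.0 : NEG) : (j == 0 ? 0.0 : NEG);
    Xp[j] = NEG;
    Yp[j] = local ? NEG : (j == 0 ? NEG : -(go + ge * (j - 1)));
    if (tb && !local && j > 1) tbY[(size_t)0 * W + j] = 3;
    if (tb && !local && j == 1) tbY[(size_t)0 * W + j] = 1;
  }

  double best = local ? 0.0 : NEG;
  int bi = 0, bj = 0;

  for (int i = 1; i <= n; ++i) {
    M[0] = NEG;
    X[0] = local ? NEG : -(go + ge * (i - 1));
    Y[0] = NEG;
    if (tb && !local) tbX[(size_t)i * W + 0] = (i == 1) ? 1 : 2;
    const int qi = q[i - 1];
    for (int j = 1; j <= m; ++j) {
      // M: consume one column from each
      double dM = Mp[j - 1], dX = Xp[j - 1], dY = Yp[j - 1];
      double h = dM; unsigned char c = 1;
      if (dX > h) { h = dX; c = 2; }
      if (dY > h) { h = dY; c = 3; }
      if (local && 0.0 > h) { h = 0.0; c = 0; }
      M[j] = h + sub(qi, s[j - 1]);
      if (tb) tbM[(size_t)i * W + j] = c;

      // X: gap in subject (consume query)
      double xo = Mp[j] - go, xe = Xp[j] - ge, xs = Yp[j] - go;
      h = xo; c = 1;
      if (xe > h) { h = xe; c = 2; }
      if (xs > h) { h = xs; c = 3; }
      X[j] = h;
      if (tb) tbX[(size_t)i * W + j] = c;

      // Y: gap in query (consume subject)
      double yo = M[j - 1] - go, ye = Y[j - 1] - ge, ys = X[j - 1] - go;
      h = yo; c = 1;
      if (ye > h) { h = ye; c = 3; }
      if (ys > h) { h = ys; c = 2; }
      Y[j] = h;
      if (tb) tbY[(size_t)i * W + j] = (c == 3) ? 3 : c;

      if (local && M[j] > best) { best = M[j]; bi = i; bj = j; }
    }
    std::swap(M, Mp); std::swap(X, Xp); std::swap(Y, Yp);
  }

  int end_state = 1;
  if (!local) {
    best = Mp[m]; end_state = 1;
    if (Xp[m] > best) { best = Xp[m]; end_state = 2; }
    if (Yp[m] > best) { best = Yp[m]; end_state = 3; }
    bi = n; bj = m;
  }

  if (score_only) {
    return List::create(_["score"] = best,
                        _["q_end"] = bi, _["s_end"] = bj);
  }

  // traceback
  std::vector<int> qa, sa;
  int i = bi, j = bj, state = end_state;
  if (local && best <= 0.0) { i = 0; j = 0; }
  while (true) {
    if (!local && i == 0 && j == 0) break;
    if (local && state == 1 && tbM[(size_t)i * W + j] == 0 && i > 0 && j > 0) {
      // local start cell: consume the match then stop
      qa.push_back(i - 1); sa.push_back(j - 1);
      --i; --j;
      break;
    }
    if (i == 0 && j == 0) break;
    unsigned char c;
    if (state == 1) {
      if (i == 0 || j == 0) break;
      c = tbM[(size_t)i * W + j];
      qa.push_back(i - 1); sa.push_back(j - 1);
      --i; --j;
    } else if (state == 2) {
      c = tbX[(size_t)i * W + j];
      qa.push_back(i - 1); sa.push_back(-1);
      --i;
    } else {
      c = tbY[(size_t)i * W + j];
      qa.push_back(-1); sa.push_back(j - 1);
      --j;
    }
    if (local && state == 1 && c == 0) break;
    state = c;
    if (state == 0) break;
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(sa.begin(), sa.end());

  int q_start = 0, s_start = 0;
  for (size_t k = 0; k < qa.size(); ++k) if (qa[k] >= 0) { q_start = qa[k]; break; }
  for (size_t k = 0; k < sa.size(); ++k) if (sa[k] >= 0) { s_start = sa[k]; break; }

  return List::create(_["score"] = best,
                      _["q_start"] = q_start, _["q_end"] = bi,
                      _["s_start"] = s_start, _["s_end"] = bj,
                      _["q_path"] = wrap(qa), _["s_path"] = wrap(sa));
}

// Global affine-gap alignment of two alignment profiles.
//
// fa, fb: S x L matrices of per-column state frequencies (gap mass simply
// contributes nothing). Column-pair score is fa_col' * sub * fb_col; gap
// penalties are applied in full per profile column. Returns the column
// paths of both profiles with -1 marking newly inserted gap columns.

// [[Rcpp::export]]
List profile_align_cpp(NumericMatrix fa, NumericMatrix fb, NumericMatrix sub,
                       double gap_open, double gap_ext) {
  const int S = fa.nrow();
  const int n = fa.ncol(), m = fb.ncol();
  const double go = gap_open + gap_ext, ge = gap_ext;

  // precompute column-pair scores
  NumericMatrix cs(n, m);
  for (int i = 0; i < n; ++i) {
    std::vector<double> proj(S, 0.0); // sub' * fa_col
    for (int y = 0; y < S; ++y) {
      double acc = 0.0;
      for (int x = 0; x < S; ++x) acc += fa(x, i) * sub(x, y);
      proj[y] = acc;
    }
    for (int j = 0; j < m; ++j) {
      double acc = 0.0;
      for (int y = 0; y < S; ++y) acc += proj[y] * fb(y, j);
      cs(i, j) = acc;
    }
  }

  std::vector<double> M(m + 1), X(m + 1), Y(m + 1);
  std::vector<double> Mp(m + 1), Xp(m + 1), Yp(m + 1);
  const size_t W = (size_t)m + 1;
  std::vector<unsigned char> tbM((size_t)(n + 1) * W, 0),
      tbX((size_t)(n + 1) * W, 0), tbY((size_t)(n + 1) * W, 0);

  for (int j = 0; j <= m; ++j) {
    Mp[j] = (j == 0) ? 0.0 : NEG;
    Xp[j] = NEG;
    Yp[j] = (j == 0) ? NEG : -(go + ge * (j - 1));
    if (j >= 1) tbY[(size_t)0 * W + j] = (j == 1) ? 1 : 3;
  }

  for (int i = 1; i <= n; ++i) {
    M[0] = NEG;
    X[0] = -(go + ge * (i - 1));
    Y[0] = NEG;
    tbX[(size_t)i * W + 0] = (i == 1) ? 1 : 2;
    for (int j = 1; j <= m; ++j) {
      double dM = Mp[j - 1], dX = Xp[j - 1], dY = Yp[j - 1];
      double h = dM; unsigned char c = 1;
      if (dX > h) { h = dX; c = 2; }
      if (dY > h) { h = dY; c = 3; }
      M[j] = h + cs(i - 1, j - 1);
      tbM[(size_t)i * W + j] = c;

      double xo = Mp[j] - go, xe = Xp[j] - ge, xs = Yp[j] - go;
      h = xo; c = 1;
      if (xe > h) { h = xe; c = 2; }
      if (xs > h) { h = xs; c = 3; }
      X[j] = h; tbX[(size_t)i * W + j] = c;

      double yo = M[j - 1] - go, ye = Y[j - 1] - ge, ys = X[j - 1] - go;
      h = yo; c = 1;
      if (ye > h) { h = ye; c = 3; }
      if (ys > h) { h = ys; c = 2; }
      Y[j] = h; tbY[(size_t)i * W + j] = c;
    }
    std::swap(M, Mp); std::swap(X, Xp); std::swap(Y, Yp);
  }

  double best = Mp[m]; int state = 1;
  if (Xp[m] > best) { best = Xp[m]; state = 2; }
  if (Yp[m] > best) { best = Yp[m]; state = 3; }

  std::vector<int> pa, pb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char c;
    if (state == 1) {
      c = tbM[(size_t)i * W + j];
      pa.push_back(i - 1); pb.push_back(j - 1);
      --i; --j;
    } else if (state == 2) {
      c = tbX[(size_t)i * W + j];
      pa.push_back(i - 1); pb.push_back(-1);
      --i;
    } else {
      c = tbY[(size_t)i * W + j];
      pa.push_back(-1); pb.push_back(j - 1);
      --j;
    }
    state = c;
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["score"] = best,
                      _["a_path"] = wrap(pa), _["b_path"] = wrap(pb));
}
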
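#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps over a precomputed
// column-pair score matrix S (nA x nB).  A gap of length L costs
// gap_open + L * gap_extend, i.e. the BLAST convention.  Returns the edit
// path as integers: 0 = align column of A with column of B, 1 = gap in B
// (consume A), 2 = gap in A (consume B).
// [[Rcpp::export(name = ".nw_affine_path")]]
IntegerVector nw_affine_path(NumericMatrix S, double gap_open,
                             double gap_extend) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e30;
  const double open_cost = -(gap_open + gap_extend);
  const double ext_cost = -gap_extend;

  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  // traceback state: which matrix the optimum came from (0=M,1=X,2=Y)
  IntegerMatrix tbM(n + 1, m + 1), tbX(n + 1, m + 1), tbY(n + 1, m + 1);

  M(0, 0) = 0.0;
  X(0, 0) = NEG;
  Y(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG;
    Y(i, 0) = NEG;
    X(i, 0) = open_cost + (i - 1) * ext_cost;
    tbX(i, 0) = 1;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG;
    X(0, j) = NEG;
    Y(0, j) = open_cost + (j - 1) * ext_cost;
    tbY(0, j) = 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: align i-1 with j-1
      double s = S(i - 1, j - 1);
      double bm = M(i - 1, j - 1), bx = X(i - 1, j - 1), by = Y(i - 1, j - 1);
      if (bm >= bx && bm >= by) { M(i, j) = bm + s; tbM(i, j) = 0; }
      else if (bx >= by)        { M(i, j) = bx + s; tbM(i, j) = 1; }
      else                      { M(i, j) = by + s; tbM(i, j) = 2; }
      // X: gap in B, consume A row i
      double xo = M(i - 1, j) + open_cost, xe = X(i - 1, j) + ext_cost;
      double xy = Y(i - 1, j) + open_cost;  // close one gap, open the other
      if (xo >= xe && xo >= xy) { X(i, j) = xo; tbX(i, j) = 0; }
      else if (xe >= xy)        { X(i, j) = xe; tbX(i, j) = 1; }
      else                      { X(i, j) = xy; tbX(i, j) = 2; }
      // Y: gap in A, consume B column j
      double yo = M(i, j - 1) + open_cost, ye = Y(i, j - 1) + ext_cost;
      double yx = X(i, j - 1) + open_cost;
      if (yo >= ye && yo >= yx) { Y(i, j) = yo; tbY(i, j) = 0; }
      else if (ye >= yx)        { Y(i, j) = ye; tbY(i, j) = 2; }
      else                      { Y(i, j) = yx; tbY(i, j) = 1; }
    }
  }

  int state;
  double em = M(n, m), ex = X(n, m), ey = Y(n, m);
  if (em >= ex && em >= ey) state = 0;
  else if (ex >= ey) state = 1;
  else state = 2;

  std::vector<int> ops;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      state = tbM(i, j);
      ops.push_back(0);
      --i; --j;
    } else if (state == 1) {
      state = tbX(i, j);
      ops.push_back(1);
      --i;
    } else {
      state = tbY(i, j);
      ops.push_back(2);
      --j;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return wrap(ops);
}

// Colinear (monotone) residue pairing on an inter-CA distance matrix.
// Maximises the number of pairs with D(i,j) <= cutoff, breaking ties by
// minimal total distance, via a Needleman-like DP.  Returns a k x 2 matrix
// of 1-based (i, j) pairs.
// [[Rcpp::export(name = ".monotone_pairs")]]
IntegerMatrix monotone_pairs(NumericMatrix D, double cutoff) {
  const int n = D.nrow(), m = D.ncol();
  const double BIG = 1e6;  // lexicographic: one pair outweighs any distance sum
  NumericMatrix V(n + 1, m + 1);
  IntegerMatrix tb(n + 1, m + 1);  // 0 = diag pair, 1 = skip i, 2 = skip j

  for (int i = 1; i <= n; ++i) tb(i, 0) = 1;
  for (int j = 1; j <= m; ++j) tb(0, j) = 2;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double best = V(i - 1, j);
      int arg = 1;
      if (V(i, j - 1) > best) { best = V(i, j - 1); arg = 2; }
      double d = D(i - 1, j - 1);
      if (d <= cutoff) {
        double w = V(i - 1, j - 1) + BIG - d;
        if (w > best) { best = w; arg = 0; }
      }
      V(i, j) = best;
      tb(i, j) = arg;
    }
  }

  std::vector<int> pi, pj;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int a = tb(i, j);
    if (a == 0) { pi.push_back(i); pj.push_back(j); --i; --j; }
    else if (a == 1) --i;
    else --j;
  }
  const int k = pi.size();
  IntegerMatrix out(k, 2);
  for (int r = 0; r < k; ++r) {
    out(r, 0) = pi[k - 1 - r];
    out(r, 1) = pj[k - 1 - r];
  }
  return out;
}
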
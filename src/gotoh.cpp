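#include <Rcpp.h>
#include <limits>
#include <vector>
using namespace Rcpp;

// Three-state affine-gap global alignment (Gotoh) minimizing
//   sum d(x_i, y_j) + sum over gaps [alpha + (len - 1) * beta].
// States: M = x_i aligned to y_j; X = gap in y (consumes x, vertical);
// Y = gap in x (consumes y, horizontal).
// Tie-break in traceback: M, then X, then Y — both for the final state and
// for each state's predecessor, giving a deterministic optimal path.
//
// xi, yi are 0-based indices into the score matrix d (rows = x residue,
// cols = y residue). Returns the optimal score and the aligned index
// vectors, with -1 marking a gap position.

static const double INF = std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(IntegerVector xi, IntegerVector yi, NumericMatrix d,
                 double alpha, double beta) {
  const int n = xi.size(), m = yi.size();
  std::vector<std::vector<double> > M(n + 1, std::vector<double>(m + 1, INF));
  std::vector<std::vector<double> > X(n + 1, std::vector<double>(m + 1, INF));
  std::vector<std::vector<double> > Y(n + 1, std::vector<double>(m + 1, INF));

  M[0][0] = 0.0;
  for (int i = 1; i <= n; ++i) X[i][0] = alpha + (i - 1) * beta;
  for (int j = 1; j <= m; ++j) Y[0][j] = alpha + (j - 1) * beta;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double dij = d(xi[i - 1], yi[j - 1]);
      double prev = std::min(M[i - 1][j - 1],
                             std::min(X[i - 1][j - 1], Y[i - 1][j - 1]));
      if (prev < INF) M[i][j] = prev + dij;
      // open from M or Y costs alpha, extend X costs beta
      double xo = std::min(M[i - 1][j] + alpha,
                           std::min(X[i - 1][j] + beta, Y[i - 1][j] + alpha));
      X[i][j] = xo;
      double yo = std::min(M[i][j - 1] + alpha,
                           std::min(X[i][j - 1] + alpha, Y[i][j - 1] + beta));
      Y[i][j] = yo;
    }
  }

  // final state: prefer M, then X, then Y on exact ties
  double best = std::min(M[n][m], std::min(X[n][m], Y[n][m]));
  int state = (M[n][m] == best) ? 0 : (X[n][m] == best) ? 1 : 2;
  if (n == 0 && m == 0) { state = 0; best = 0.0; }

  std::vector<int> ax, ay;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    // re-derive each cell's argmin from the stored values (same arithmetic
    // as the forward pass, so exact comparisons are safe)
    if (state == 0) {
      ax.push_back(xi[i - 1]);
      ay.push_back(yi[j - 1]);
      --i; --j;
      double prev = std::min(M[i][j], std::min(X[i][j], Y[i][j]));
      state = (M[i][j] == prev) ? 0 : (X[i][j] == prev) ? 1 : 2;
    } else if (state == 1) {
      ax.push_back(xi[i - 1]);
      ay.push_back(-1);
      --i;
      double cM = M[i][j] + alpha, cX = X[i][j] + beta, cY = Y[i][j] + alpha;
      double v = std::min(cM, std::min(cX, cY));
      state = (cM == v) ? 0 : (cX == v) ? 1 : 2;
    } else {
      ax.push_back(-1);
      ay.push_back(yi[j - 1]);
      --j;
      double cM = M[i][j] + alpha, cX = X[i][j] + alpha, cY = Y[i][j] + beta;
      double v = std::min(cM, std::min(cX, cY));
      state = (cM == v) ? 0 : (cX == v) ? 1 : 2;
    }
  }
  std::reverse(ax.begin(), ax.end());
  std::reverse(ay.begin(), ay.end());
  return List::create(_["score"] = best,
                      _["ax"] = IntegerVector(ax.begin(), ax.end()),
                      _["ay"] = IntegerVector(ay.begin(), ay.end()));
}
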
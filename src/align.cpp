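// Global pairwise alignment with affine gap costs (Gotoh three-state DP).
// Scores are maximized; a gap of length L costs gap_open + L * gap_extend,
// so gap_open = 0 gives the linear-gap model.  Traceback is deterministic:
// at every tie the diagonal (match) state is preferred, then the vertical
// state (gap in b, consuming a), then the horizontal state (gap in a).

#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double NEG = -1e300;

// a, b: 0-based indices into the substitution matrix rows/cols
// [[Rcpp::export(name = ".align_global")]]
List align_global(IntegerVector a, IntegerVector b, NumericMatrix sub,
                  double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("sequences must be nonempty");
  const double open = gap_open + gap_extend;   // cost of the first gap column

  // state codes: 0 = M (diagonal), 1 = X (up, gap in b), 2 = Y (left, gap in a)
  std::vector<double> M((n + 1) * (m + 1), NEG), X = M, Y = M;
  std::vector<unsigned char> pM((n + 1) * (m + 1), 0), pX = pM, pY = pM;
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[at(i, 0)] = -gap_open - i * gap_extend;
    pX[at(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[at(0, j)] = -gap_open - j * gap_extend;
    pY[at(0, j)] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: consume a[i-1] and b[j-1]
      {
        const double s = sub(a[i - 1], b[j - 1]);
        const double vm = M[at(i - 1, j - 1)], vx = X[at(i - 1, j - 1)],
                     vy = Y[at(i - 1, j - 1)];
        double best = vm; unsigned char p = 0;
        if (vx > best) { best = vx; p = 1; }
        if (vy > best) { best = vy; p = 2; }
        M[at(i, j)] = best + s; pM[at(i, j)] = p;
      }
      // X: consume a[i-1] against a gap
      {
        const double vm = M[at(i - 1, j)] - open,
                     vx = X[at(i - 1, j)] - gap_extend,
                     vy = Y[at(i - 1, j)] - open;
        double best = vm; unsigned char p = 0;
        if (vx > best) { best = vx; p = 1; }
        if (vy > best) { best = vy; p = 2; }
        X[at(i, j)] = best; pX[at(i, j)] = p;
      }
      // Y: consume b[j-1] against a gap
      {
        const double vm = M[at(i, j - 1)] - open,
                     vy = Y[at(i, j - 1)] - gap_extend,
                     vx = X[at(i, j - 1)] - open;
        double best = vm; unsigned char p = 0;
        if (vx > best) { best = vx; p = 1; }
        if (vy > best) { best = vy; p = 2; }
        Y[at(i, j)] = best; pY[at(i, j)] = p;
      }
    }
  }

  const double vm = M[at(n, m)], vx = X[at(n, m)], vy = Y[at(n, m)];
  double score = vm; int state = 0;
  if (vx > score) { score = vx; state = 1; }
  if (vy > score) { score = vy; state = 2; }

  // traceback: emit 1-based residue positions, 0 for a gap
  std::vector<int> pa, pb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      const unsigned char p = pM[at(i, j)];
      pa.push_back(i); pb.push_back(j);
      --i; --j; state = p;
    } else if (state == 1) {
      const unsigned char p = pX[at(i, j)];
      pa.push_back(i); pb.push_back(0);
      --i; state = p;
    } else {
      const unsigned char p = pY[at(i, j)];
      pa.push_back(0); pb.push_back(j);
      --j; state = p;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["score"] = score,
                      _["a_pos"] = IntegerVector(pa.begin(), pa.end()),
                      _["b_pos"] = IntegerVector(pb.begin(), pb.end()));
}
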
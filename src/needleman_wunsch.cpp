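#include <Rcpp.h>
#include <limits>
#include <string>
#include <vector>
using namespace Rcpp;

// Gotoh three-state global alignment. A gap of length L costs
// gapOpen + (L - 1) * gapExtend, so equal open/extend gives the linear model.
// Traceback is deterministic with state preference M (diagonal) > X (gap in
// b, consuming a, "up") > Y (gap in a, "left"); within the X/Y recurrences
// ties prefer continuing from M.

// [[Rcpp::export(name = ".nw_align")]]
List nw_align(std::string a, std::string b, NumericMatrix score,
              CharacterVector alphabet, double gapOpen, double gapExtend) {
  const int n = a.size(), m = b.size();
  const double NEG = -std::numeric_limits<double>::infinity();

  std::vector<int> code(256, -1);
  for (int k = 0; k < alphabet.size(); ++k) {
    std::string s = as<std::string>(alphabet[k]);
    code[(unsigned char)s[0]] = k;
  }
  std::vector<int> ca(n), cb(m);
  for (int i = 0; i < n; ++i) {
    ca[i] = code[(unsigned char)a[i]];
    if (ca[i] < 0) stop("symbol '%s' (sequence a, position %d) outside matrix alphabet",
                        std::string(1, a[i]), i + 1);
  }
  for (int j = 0; j < m; ++j) {
    cb[j] = code[(unsigned char)b[j]];
    if (cb[j] < 0) stop("symbol '%s' (sequence b, position %d) outside matrix alphabet",
                        std::string(1, b[j]), j + 1);
  }

  // state matrices and traceback (0 = M, 1 = X, 2 = Y)
  std::vector<double> M((n + 1) * (m + 1), NEG), X((n + 1) * (m + 1), NEG),
      Y((n + 1) * (m + 1), NEG);
  std::vector<signed char> tbM((n + 1) * (m + 1), -1),
      tbX((n + 1) * (m + 1), -1), tbY((n + 1) * (m + 1), -1);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[at(i, 0)] = gapOpen + (i - 1) * gapExtend;
    tbX[at(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[at(0, j)] = gapOpen + (j - 1) * gapExtend;
    tbY[at(0, j)] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = score(ca[i - 1], cb[j - 1]);
      // M: from any state at (i-1, j-1); prefer M > X > Y on ties
      {
        double best = M[at(i - 1, j - 1)];
        signed char arg = 0;
        if (X[at(i - 1, j - 1)] > best) { best = X[at(i - 1, j - 1)]; arg = 1; }
        if (Y[at(i - 1, j - 1)] > best) { best = Y[at(i - 1, j - 1)]; arg = 2; }
        if (best > NEG) { M[at(i, j)] = best + s; tbM[at(i, j)] = arg; }
      }
      // X: consume a[i-1] against a gap; ties prefer extending the open gap
      // so equal-scoring optima keep gaps contiguous
      {
        double vM = M[at(i - 1, j)] > NEG ? M[at(i - 1, j)] + gapOpen : NEG;
        double vX = X[at(i - 1, j)] > NEG ? X[at(i - 1, j)] + gapExtend : NEG;
        double vY = Y[at(i - 1, j)] > NEG ? Y[at(i - 1, j)] + gapOpen : NEG;
        double best = vX; signed char arg = 1;
        if (vM > best) { best = vM; arg = 0; }
        if (vY > best) { best = vY; arg = 2; }
        if (best > NEG) { X[at(i, j)] = best; tbX[at(i, j)] = arg; }
      }
      // Y: consume b[j-1] against a gap
      {
        double vM = M[at(i, j - 1)] > NEG ? M[at(i, j - 1)] + gapOpen : NEG;
        double vX = X[at(i, j - 1)] > NEG ? X[at(i, j - 1)] + gapOpen : NEG;
        double vY = Y[at(i, j - 1)] > NEG ? Y[at(i, j - 1)] + gapExtend : NEG;
        double best = vY; signed char arg = 2;
        if (vM > best) { best = vM; arg = 0; }
        if (vX > best) { best = vX; arg = 1; }
        if (best > NEG) { Y[at(i, j)] = best; tbY[at(i, j)] = arg; }
      }
    }
  }

  double best = M[at(n, m)];
  int state = 0;
  if (X[at(n, m)] > best) { best = X[at(n, m)]; state = 1; }
  if (Y[at(n, m)] > best) { best = Y[at(n, m)]; state = 2; }

  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      signed char prev = tbM[at(i, j)];
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j; state = prev;
    } else if (state == 1) {
      signed char prev = tbX[at(i, j)];
      ra.push_back(a[i - 1]); rb.push_back('-');
      --i; state = prev;
    } else {
      signed char prev = tbY[at(i, j)];
      ra.push_back('-'); rb.push_back(b[j - 1]);
      --j; state = prev;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  int matches = 0, comparable = 0;
  for (size_t k = 0; k < ra.size(); ++k) {
    if (ra[k] != '-' && rb[k] != '-') {
      ++comparable;
      if (ra[k] == rb[k]) ++matches;
    }
  }
  double ident = comparable > 0 ? 100.0 * matches / comparable : 0.0;

  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = best, _["identity_percent"] = ident);
}
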
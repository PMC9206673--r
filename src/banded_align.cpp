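// Banded Gotoh alignment with optional free end gaps.
//
// Scores: match/mismatch per column; a gap of length L scores
// gap_open + (L-1) * gap_extend (both negative).  The band constrains the
// diagonal j - i to [-band, band], so the caller must choose
// band >= |nchar(a) - nchar(b)| plus expected indel drift.

#include <Rcpp.h>
#include <cstring>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double NEG = -1e18;

// [[Rcpp::export(name = ".banded_align_stats")]]
List banded_align_stats(std::string a, std::string b,
                        double match, double mismatch,
                        double gap_open, double gap_extend,
                        int band, bool free_ends) {
  const int n = (int) a.size(), m = (int) b.size();
  const int W = 2 * band + 1;
  if (std::abs(n - m) > band && !free_ends)
    stop("band too narrow for the length difference");
  std::vector<double> M((size_t)(n + 1) * W, NEG), X = M, Y = M;
  std::vector<unsigned char> pM((size_t)(n + 1) * W, 0), pX = pM, pY = pM;
  // ptr codes -- M: 1 from M, 2 from X, 3 from Y, 4 fresh start
  //              X: 1 from M, 2 from X;  Y: 1 from M, 3 from Y
  auto off = [band](int i, int j) { return j - i + band; };
  auto at = [&](std::vector<double> &v, int i, int j) -> double & {
    return v[(size_t) i * W + off(i, j)];
  };
  auto pat = [&](std::vector<unsigned char> &v, int i, int j)
      -> unsigned char & { return v[(size_t) i * W + off(i, j)]; };
  auto inband = [&](int i, int j) {
    return j >= 0 && j <= m && off(i, j) >= 0 && off(i, j) < W;
  };
  // row 0
  for (int j = 0; j <= m && j <= band; ++j) {
    if (j == 0) { at(M, 0, 0) = 0; pat(pM, 0, 0) = 4; }
    else if (free_ends) { at(M, 0, j) = 0; pat(pM, 0, j) = 4; }
    else {
      at(Y, 0, j) = gap_open + (j - 1) * gap_extend;
      pat(pY, 0, j) = (j == 1) ? 1 : 3;
    }
  }
  for (int i = 1; i <= n; ++i) {
    int jlo = std::max(0, i - band), jhi = std::min(m, i + band);
    for (int j = jlo; j <= jhi; ++j) {
      if (j == 0) {
        if (free_ends) { at(M, i, 0) = 0; pat(pM, i, 0) = 4; }
        else {
          at(X, i, 0) = gap_open + (i - 1) * gap_extend;
          pat(pX, i, 0) = (i == 1) ? 1 : 2;
        }
        continue;
      }
      // M: diagonal
      if (inband(i - 1, j - 1)) {
        double prev = at(M, i - 1, j - 1); unsigned char pc = 1;
        if (at(X, i - 1, j - 1) > prev) { prev = at(X, i - 1, j - 1); pc = 2; }
        if (at(Y, i - 1, j - 1) > prev) { prev = at(Y, i - 1, j - 1); pc = 3; }
        if (prev > NEG / 2) {
          double s = (a[i - 1] == b[j - 1] && a[i - 1] != 'N') ? match
                                                               : mismatch;
          at(M, i, j) = prev + s;
          pat(pM, i, j) = pc;
        }
      }
      // X: gap in b (consume a[i]); no direct X<->Y adjacency
      if (inband(i - 1, j)) {
        double fromM = at(M, i - 1, j) > NEG / 2 ? at(M, i - 1, j) + gap_open
                                                 : NEG;
        double fromX = at(X, i - 1, j) > NEG / 2
                           ? at(X, i - 1, j) + gap_extend : NEG;
        if (fromM >= fromX) { at(X, i, j) = fromM; pat(pX, i, j) = 1; }
        else { at(X, i, j) = fromX; pat(pX, i, j) = 2; }
      }
      // Y: gap in a (consume b[j])
      if (inband(i, j - 1)) {
        double fromM = at(M, i, j - 1) > NEG / 2 ? at(M, i, j - 1) + gap_open
                                                 : NEG;
        double fromY = at(Y, i, j - 1) > NEG / 2
                           ? at(Y, i, j - 1) + gap_extend : NEG;
        if (fromM >= fromY) { at(Y, i, j) = fromM; pat(pY, i, j) = 1; }
        else { at(Y, i, j) = fromY; pat(pY, i, j) = 3; }
      }
    }
  }
  // best end cell: (n, m) for global; any last-row/last-col cell when free
  double best = NEG; int bi = n, bj = m; char bs = 'M';
  auto consider = [&](int i, int j) {
    if (!inband(i, j)) return;
    if (at(M, i, j) > best) { best = at(M, i, j); bi = i; bj = j; bs = 'M'; }
    if (at(X, i, j) > best) { best = at(X, i, j); bi = i; bj = j; bs = 'X'; }
    if (at(Y, i, j) > best) { best = at(Y, i, j); bi = i; bj = j; bs = 'Y'; }
  };
  if (free_ends) {
    for (int j = 0; j <= m; ++j) consider(n, j);
    for (int i = 0; i <= n; ++i) consider(i, m);
  } else {
    consider(n, m);
  }
  if (best <= NEG / 2)
    return List::create(_["score"] = R_NegInf, _["matches"] = 0,
                        _["columns"] = 0);
  // traceback
  int i = bi, j = bj, matches = 0, columns = 0;
  char st = bs;
  while (i > 0 || j > 0) {
    if (st == 'M') {
      if (i == 0 || j == 0) break;      // free leading gap / start marker
      unsigned char pc = pat(pM, i, j);
      ++columns;
      if (a[i - 1] == b[j - 1] && a[i - 1] != 'N') ++matches;
      --i; --j;
      if (pc == 1) st = 'M';
      else if (pc == 2) st = 'X';
      else if (pc == 3) st = 'Y';
      else break;                       // fresh start (free end gaps)
    } else if (st == 'X') {
      if (i == 0) break;
      unsigned char pc = pat(pX, i, j);
      ++columns;
      --i;
      st = (pc == 2) ? 'X' : 'M';
    } else {
      if (j == 0) break;
      unsigned char pc = pat(pY, i, j);
      ++columns;
      --j;
      st = (pc == 3) ? 'Y' : 'M';
    }
  }
  return List::create(_["score"] = best, _["matches"] = matches,
                      _["columns"] = columns,
                      _["a_start"] = i, _["b_start"] = j,
                      _["a_end"] = bi, _["b_end"] = bj);
}
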
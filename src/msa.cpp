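#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cmath>
#include "iupac.h"

using namespace Rcpp;

// Progressive multiple alignment support: 6-mer profile distances for the
// guide tree, and a banded global profile-profile merge (Gotoh three-state
// DP over alignment columns).

namespace {

const int NSYM = 6;  // A C G T N -
static const float NEG_INF_F = -1e30f;

inline int sym_index(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2;
    case 'T': return 3; case 'N': return 4; case '-': return 5;
    default: return 4;  // unexpected characters behave like N
  }
}

// pairwise symbol scores: bases via IUPAC compatibility, existing gaps score
// gap_extend against a base and 0 against another gap
inline double sym_score(int a, int b, double ma, double mi, double ge) {
  if (a == 5 && b == 5) return 0.0;
  if (a == 5 || b == 5) return ge;
  if (a == 4 || b == 4) return ma;  // N is compatible with any base
  return a == b ? ma : mi;
}

}  // namespace

// Fraction-of-shared-6-mers distance matrix used to order profile merges.
// [[Rcpp::export]]
NumericMatrix cpp_kmer_dist(CharacterVector seqs, int k) {
  int n = seqs.size();
  int ncodes = 1 << (2 * k);
  std::vector<std::vector<int>> counts(n, std::vector<int>(ncodes, 0));
  std::vector<int> totals(n, 0);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    int code = 0, valid = 0;
    for (size_t p = 0; p < s.size(); ++p) {
      int b;
      switch (s[p]) {
        case 'A': b = 0; break; case 'C': b = 1; break;
        case 'G': b = 2; break; case 'T': b = 3; break;
        default: b = -1;
      }
      if (b < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | b) & (ncodes - 1);
      if (++valid >= k) { counts[i][code]++; totals[i]++; }
    }
  }
  NumericMatrix d(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      long shared = 0;
      for (int c = 0; c < ncodes; ++c)
        shared += std::min(counts[i][c], counts[j][c]);
      int mn = std::min(totals[i], totals[j]);
      double dist = mn > 0 ? 1.0 - (double)shared / mn : 1.0;
      d(i, j) = dist; d(j, i) = dist;
    }
  }
  return d;
}

// Merge two alignments (vectors of equal-length gapped rows) by banded global
// alignment of their column profiles.  Returns rows of A then rows of B,
// re-gapped to a common width.
// [[Rcpp::export]]
CharacterVector cpp_merge_profiles(CharacterVector A, CharacterVector B,
                                   double match, double mismatch,
                                   double gap_open, double gap_extend,
                                   int band_extra) {
  int nA = A.size(), nB = B.size();
  std::vector<std::string> ra(nA), rb(nB);
  for (int i = 0; i < nA; ++i) ra[i] = as<std::string>(A[i]);
  for (int i = 0; i < nB; ++i) rb[i] = as<std::string>(B[i]);
  const int W1 = nA ? (int)ra[0].size() : 0;
  const int W2 = nB ? (int)rb[0].size() : 0;
  if (W1 == 0 || W2 == 0) stop("cannot merge empty profiles");

  // column frequency profiles, column-major so each cell's six values share
  // a cache line
  std::vector<float> fa((size_t)NSYM * W1, 0.0f), fb((size_t)NSYM * W2, 0.0f);
  for (int r = 0; r < nA; ++r)
    for (int c = 0; c < W1; ++c)
      fa[(size_t)c * NSYM + sym_index(ra[r][c])] += 1.0f / nA;
  for (int r = 0; r < nB; ++r)
    for (int c = 0; c < W2; ++c)
      fb[(size_t)c * NSYM + sym_index(rb[r][c])] += 1.0f / nB;

  // per-column of B: expected score against each pure symbol
  std::vector<float> sb((size_t)NSYM * W2, 0.0f);
  for (int c = 0; c < W2; ++c)
    for (int a = 0; a < NSYM; ++a) {
      double v = 0.0;
      for (int b = 0; b < NSYM; ++b)
        v += fb[(size_t)c * NSYM + b] * sym_score(a, b, match, mismatch, gap_extend);
      sb[(size_t)c * NSYM + a] = (float)v;
    }

  const int band = std::max(60, std::abs(W1 - W2) + 40) + band_extra;
  const size_t W = (size_t)W2 + 1;
  const size_t cells = (size_t)(W1 + 1) * W;
  static std::vector<float> M, X, Y;
  static std::vector<unsigned char> tbM, tbX, tbY;
  if (M.size() < cells) {
    M.resize(cells); X.resize(cells); Y.resize(cells);
    tbM.resize(cells); tbX.resize(cells); tbY.resize(cells);
  }
  const float fgo = (float)gap_open, fge = (float)gap_extend;

  // boundaries (row 0 full width; column 0 all rows)
  for (int j = 0; j <= W2; ++j) {
    M[j] = NEG_INF_F; X[j] = NEG_INF_F; Y[j] = NEG_INF_F;
  }
  M[0] = 0.0f;
  for (int j = 1; j <= W2; ++j) Y[j] = fgo + fge * j;
  for (int i = 1; i <= W1; ++i) {
    size_t r = (size_t)i * W;
    M[r] = NEG_INF_F; Y[r] = NEG_INF_F;
    X[r] = fgo + fge * i;
  }

  int prev_lo = 0, prev_hi = W2;
  for (int i = 1; i <= W1; ++i) {
    int c = (int)std::llround((double)i * W2 / W1);
    int jlo = std::max(1, c - band), jhi = std::min(W2, c + band);
    size_t row = (size_t)i * W, prow = row - W;
    // neutralise stale previous-row cells this row can read
    for (int j = std::max(1, jlo - 1); j <= jhi; ++j)
      if (j < prev_lo || j > prev_hi) {
        M[prow + j] = NEG_INF_F; X[prow + j] = NEG_INF_F; Y[prow + j] = NEG_INF_F;
      }
    if (jlo - 1 >= 1) {
      M[row + jlo - 1] = NEG_INF_F; X[row + jlo - 1] = NEG_INF_F; Y[row + jlo - 1] = NEG_INF_F;
    }
    if (jhi + 1 <= W2) {
      M[row + jhi + 1] = NEG_INF_F; X[row + jhi + 1] = NEG_INF_F; Y[row + jhi + 1] = NEG_INF_F;
    }
    const float* fai = &fa[(size_t)(i - 1) * NSYM];
    for (int j = jlo; j <= jhi; ++j) {
      // expected column-vs-column score
      const float* sbj = &sb[(size_t)(j - 1) * NSYM];
      float sc = fai[0] * sbj[0] + fai[1] * sbj[1] + fai[2] * sbj[2] +
                 fai[3] * sbj[3] + fai[4] * sbj[4] + fai[5] * sbj[5];
      float dM = M[prow + j - 1], dX = X[prow + j - 1], dY = Y[prow + j - 1];
      float best = dM; unsigned char code = 0;
      if (dX > best) { best = dX; code = 1; }
      if (dY > best) { best = dY; code = 2; }
      M[row + j] = (best <= NEG_INF_F / 2) ? NEG_INF_F : (float)sc + best;
      tbM[row + j] = code;

      float xM = M[prow + j] + fgo + fge, xX = X[prow + j] + fge,
            xY = Y[prow + j] + fgo + fge;
      float xb = xM; unsigned char xc = 0;
      if (xX > xb) { xb = xX; xc = 1; }
      if (xY > xb) { xb = xY; xc = 2; }
      X[row + j] = (xb <= NEG_INF_F / 2) ? NEG_INF_F : xb;
      tbX[row + j] = xc;

      float yM = M[row + j - 1] + fgo + fge, yY = Y[row + j - 1] + fge,
            yX = X[row + j - 1] + fgo + fge;
      float yb = yM; unsigned char yc = 0;
      if (yY > yb) { yb = yY; yc = 2; }
      if (yX > yb) { yb = yX; yc = 1; }
      Y[row + j] = (yb <= NEG_INF_F / 2) ? NEG_INF_F : yb;
      tbY[row + j] = yc;
    }
    prev_lo = jlo; prev_hi = jhi;
  }

  // traceback from (W1, W2)
  size_t endc = (size_t)W1 * W + W2;
  int state = 0;
  float bestend = M[endc];
  if (X[endc] > bestend) { bestend = X[endc]; state = 1; }
  if (Y[endc] > bestend) { bestend = Y[endc]; state = 2; }
  if (bestend <= NEG_INF_F / 2) stop("profile merge band too narrow");

  std::vector<char> ops;  // 'D' diag, 'U' up (A col), 'L' left (B col)
  int i = W1, j = W2;
  while (i > 0 || j > 0) {
    if (i == 0) { ops.push_back('L'); --j; continue; }
    if (j == 0) { ops.push_back('U'); --i; continue; }
    size_t c = (size_t)i * W + j;
    if (state == 0) { ops.push_back('D'); state = tbM[c]; --i; --j; }
    else if (state == 1) { ops.push_back('U'); state = tbX[c]; --i; }
    else { ops.push_back('L'); state = tbY[c]; --j; }
  }
  std::reverse(ops.begin(), ops.end());

  int Wm = (int)ops.size();
  CharacterVector out(nA + nB);
  std::string buf(Wm, '-');
  for (int r = 0; r < nA; ++r) {
    int ci = 0;
    for (int p = 0; p < Wm; ++p)
      buf[p] = (ops[p] == 'L') ? '-' : ra[r][ci++];
    out[r] = buf;
  }
  for (int r = 0; r < nB; ++r) {
    int cj = 0;
    for (int p = 0; p < Wm; ++p)
      buf[p] = (ops[p] == 'U') ? '-' : rb[r][cj++];
    out[nA + r] = buf;
  }
  return out;
}
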
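#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cmath>
#include "iupac.h"

using namespace Rcpp;

// Windowed tandem-repeat scan.  Semantics: for window sizes descending from
// wmax to wmin, a position i carries a repeat of period w when the identity
// between the co-occurring segments s[i, i+w) and s[i+w, i+2w) meets a
// similarity threshold that diminishes linearly with window size; hits are
// extended to count consecutive copies and the winning (largest-window-first,
// leftmost) repeat claims its span so smaller windows cannot re-report it.
//
// Candidate (position, period) pairs are restricted to exact shared k-mers at
// in-range distances (k = min(8, wmin)); candidates are verified with a
// Hamming fast-accept followed by a banded global-alignment identity, so the
// scan has the same accept/reject behaviour as an exhaustive sweep on both
// planted repeats and repeat-free sequence at a fraction of the cost.

namespace {

double thr_for_window(int w, int wmin, int wmax, double thr_min, double thr_max) {
  if (wmax == wmin) return thr_min;
  return thr_min + (thr_max - thr_min) * (double)(w - wmin) / (double)(wmax - wmin);
}

double hamming_identity(const std::string& s, int i1, int i2, int w) {
  int eq = 0;
  for (int k = 0; k < w; ++k)
    if (s[i1 + k] == s[i2 + k]) ++eq;
  return 100.0 * eq / w;
}

}  // namespace

List cpp_pairwise_align(std::string query, std::string target, int mode,
                        double match, double mismatch, double gap_open,
                        double gap_extend, bool degenerate, int band);

namespace {

// identity between two equal-length windows: Hamming fast path, otherwise a
// banded global alignment counting identity over all columns
double window_pair_identity(const std::string& s, int i1, int i2, int w,
                            double thr, double ma, double mi, double go,
                            double ge) {
  double ham = hamming_identity(s, i1, i2, w);
  if (ham >= thr) return ham;
  int band = std::max(8, w / 4);
  List a = cpp_pairwise_align(s.substr(i1, w), s.substr(i2, w), 1, ma, mi, go,
                              ge, true, band);
  return as<double>(a["identity_pct"]);
}

struct Claim { int lo, hi; };  // 0-based half-open

bool overlaps(const std::vector<Claim>& claims, int lo, int hi) {
  for (const Claim& c : claims)
    if (lo < c.hi && c.lo < hi) return true;
  return false;
}

}  // namespace

// [[Rcpp::export]]
DataFrame cpp_tandem_scan(std::string s, int wmin, int wmax,
                          double thr_at_min, double thr_at_max,
                          double match, double mismatch, double gap_open,
                          double gap_extend) {
  const int L = (int)s.size();
  std::vector<int> r_start, r_window, r_ncopies;
  std::vector<double> r_identity;
  if (L >= 2 * wmin && wmin >= 2) {
    const int k = std::min(8, wmin);
    const int ncodes = 1 << (2 * k);
    // k-mer positions (skip k-mers with non-ACGT characters)
    std::vector<std::vector<int>> buckets(ncodes);
    {
      int code = 0, valid = 0;
      for (int p = 0; p < L; ++p) {
        int b;
        switch (s[p]) {
          case 'A': b = 0; break; case 'C': b = 1; break;
          case 'G': b = 2; break; case 'T': b = 3; break;
          default: b = -1;
        }
        if (b < 0) { valid = 0; code = 0; continue; }
        code = ((code << 2) | b) & (ncodes - 1);
        if (++valid >= k) buckets[code].push_back(p - k + 1);
      }
    }
    const int dmax = std::min(wmax, L / 2);
    std::vector<std::vector<int>> anchors(dmax + 1);
    long total_anchors = 0;
    for (int c = 0; c < ncodes && total_anchors < 2000000; ++c) {
      const std::vector<int>& b = buckets[c];
      for (size_t a = 0; a < b.size(); ++a) {
        for (size_t e = a + 1; e < b.size(); ++e) {
          int d = b[e] - b[a];
          if (d > dmax) break;
          if (d < wmin) continue;
          anchors[d].push_back(b[a]);
          ++total_anchors;
        }
      }
    }

    std::vector<Claim> claims;
    for (int d = dmax; d >= wmin; --d) {
      std::vector<int>& pos = anchors[d];
      if (pos.empty()) continue;
      std::sort(pos.begin(), pos.end());
      pos.erase(std::unique(pos.begin(), pos.end()), pos.end());
      double thr = thr_for_window(d, wmin, wmax, thr_at_min, thr_at_max);
      for (int i : pos) {
        if (i + 2 * d > L) continue;
        if (overlaps(claims, i, i + 2 * d)) continue;
        double id = window_pair_identity(s, i, i + d, d, thr, match, mismatch,
                                         gap_open, gap_extend);
        if (id < thr) continue;
        // count consecutive copies by adjacent-pair identity
        int ncopies = 2;
        while (i + (ncopies + 1) * d <= L) {
          double idn = window_pair_identity(s, i + (ncopies - 1) * d,
                                            i + ncopies * d, d, thr, match,
                                            mismatch, gap_open, gap_extend);
          if (idn < thr) break;
          ++ncopies;
        }
        int hi = i + ncopies * d;
        if (overlaps(claims, i, hi)) continue;
        claims.push_back({i, hi});
        r_start.push_back(i);
        r_window.push_back(d);
        r_ncopies.push_back(ncopies);
        r_identity.push_back(id);
      }
    }
  }
  // report sorted by start
  std::vector<int> ord(r_start.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int)i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return r_start[a] < r_start[b]; });
  IntegerVector st(ord.size()), wd(ord.size()), nc(ord.size());
  NumericVector idp(ord.size());
  for (size_t i = 0; i < ord.size(); ++i) {
    st[i] = r_start[ord[i]]; wd[i] = r_window[ord[i]];
    nc[i] = r_ncopies[ord[i]]; idp[i] = r_identity[ord[i]];
  }
  return DataFrame::create(_["start0"] = st, _["window"] = wd,
                           _["n_copies"] = nc, _["identity_pct"] = idp);
}
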
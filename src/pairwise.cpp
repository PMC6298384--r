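#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>
#include "iupac.h"

using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh three-state DP) over nucleotide
// strings, with IUPAC-degenerate-aware scoring and an optional band around
// the length-scaled diagonal.  A gap of length k costs gap_open + k*gap_extend
// (both supplied as non-positive numbers).
//
// Modes: 0 = local (Smith-Waterman), 1 = global (Needleman-Wunsch),
// 2 = ends-free / overlap (terminal gaps in either sequence are free and the
// reported alignment covers only the anchored region).

static const float NEG_INF_F = -1e30f;

namespace {

struct Workspace {
  std::vector<float> M, X, Y;
  std::vector<unsigned char> tbM, tbX, tbY;
  std::vector<int> rlo, rhi;
  void ensure(size_t cells, size_t rows) {
    if (M.size() < cells) {
      M.resize(cells); X.resize(cells); Y.resize(cells);
      tbM.resize(cells); tbX.resize(cells); tbY.resize(cells);
    }
    if (rlo.size() < rows) { rlo.resize(rows); rhi.resize(rows); }
  }
};

Workspace& ws() {
  static Workspace w;
  return w;
}

enum TB { TB_M = 0, TB_X = 1, TB_Y = 2, TB_START = 3 };

struct AlnOut {
  double score;
  int qs, qe, ts, te;      // 0-based half-open spans
  std::string qaln, taln;  // gapped strings over the aligned region
  int matches, mismatches, gapcols;
  bool empty;
};

AlnOut align_core(const std::string& q, const std::string& t, int mode,
                  double ma, double mi, double go, double ge,
                  bool degen, int band) {
  const int n = (int)q.size(), m = (int)t.size();
  const size_t W = (size_t)m + 1;
  Workspace& w = ws();
  w.ensure(((size_t)n + 1) * W, (size_t)n + 1);
  float* M = w.M.data();
  float* X = w.X.data();
  float* Y = w.Y.data();
  unsigned char* tbM = w.tbM.data();
  unsigned char* tbX = w.tbX.data();
  unsigned char* tbY = w.tbY.data();

  const float fgo = (float)go, fge = (float)ge;
  const float fmatch = (float)ma, fmis = (float)mi;

  // row 0
  for (int j = 0; j <= m; ++j) {
    size_t c = (size_t)j;
    M[c] = NEG_INF_F; X[c] = NEG_INF_F; Y[c] = NEG_INF_F;
    if (mode == 1) {
      if (j == 0) M[c] = 0.0f;
      else Y[c] = fgo + fge * j;
    } else {
      M[c] = 0.0f;  // free start anywhere on the boundary
    }
  }
  w.rlo[0] = 0; w.rhi[0] = m;

  float best_local = 0.0f;
  int bi = 0, bj = 0;

  static std::vector<int> tmask_buf;
  if ((int)tmask_buf.size() < m) tmask_buf.resize(m);
  int* tmask = tmask_buf.data();
  for (int j = 0; j < m; ++j) tmask[j] = iupac_mask(t[j]);

  int prev_lo = 0, prev_hi = m;
  for (int i = 1; i <= n; ++i) {
    int jlo = 1, jhi = m;
    if (band > 0) {
      int c = (int)std::llround((double)i * m / n);
      jlo = std::max(1, c - band);
      jhi = std::min(m, c + band);
    }
    w.rlo[i] = jlo; w.rhi[i] = jhi;
    size_t row = (size_t)i * W, prow = row - W;

    // neutralise stale cells of the previous row that this row can read
    for (int j = jlo - 1; j <= jhi; ++j) {
      if (j < 0) continue;
      if (j < prev_lo || j > prev_hi) {
        if (!(j == 0)) { M[prow + j] = NEG_INF_F; X[prow + j] = NEG_INF_F; Y[prow + j] = NEG_INF_F; }
      }
    }
    // column 0 of this row
    M[row] = NEG_INF_F; X[row] = NEG_INF_F; Y[row] = NEG_INF_F;
    if (mode == 1) X[row] = fgo + fge * i;
    else M[row] = 0.0f;
    // guard cell just past the band
    if (jhi + 1 <= m) { M[row + jhi + 1] = NEG_INF_F; X[row + jhi + 1] = NEG_INF_F; Y[row + jhi + 1] = NEG_INF_F; }
    if (jlo - 1 >= 1) { M[row + jlo - 1] = NEG_INF_F; X[row + jlo - 1] = NEG_INF_F; Y[row + jlo - 1] = NEG_INF_F; }

    const char qc = q[i - 1];
    const int qmask = iupac_mask(qc);
    for (int j = jlo; j <= jhi; ++j) {
      float sc = degen ? ((qmask & tmask[j - 1]) ? fmatch : fmis)
                       : ((qc == t[j - 1] && qmask) ? fmatch : fmis);
      // M state
      float dM = M[prow + j - 1], dX = X[prow + j - 1], dY = Y[prow + j - 1];
      float best = dM; unsigned char code = TB_M;
      if (dX > best) { best = dX; code = TB_X; }
      if (dY > best) { best = dY; code = TB_Y; }
      if (mode == 0 && 0.0f > best) { best = 0.0f; code = TB_START; }
      float mval = (best <= NEG_INF_F / 2) ? NEG_INF_F : sc + best;
      M[row + j] = mval; tbM[row + j] = code;
      if (mode == 0 && mval > best_local) { best_local = mval; bi = i; bj = j; }

      // X: gap in target (consume query char)
      float xM = M[prow + j] + fgo + fge;
      float xX = X[prow + j] + fge;
      float xY = Y[prow + j] + fgo + fge;
      float xbest = xM; unsigned char xcode = TB_M;
      if (xX > xbest) { xbest = xX; xcode = TB_X; }
      if (xY > xbest) { xbest = xY; xcode = TB_Y; }
      X[row + j] = (xbest <= NEG_INF_F / 2) ? NEG_INF_F : xbest;
      tbX[row + j] = xcode;

      // Y: gap in query (consume target char)
      float yM = M[row + j - 1] + fgo + fge;
      float yY = Y[row + j - 1] + fge;
      float yX = X[row + j - 1] + fgo + fge;
      float ybest = yM; unsigned char ycode = TB_M;
      if (yY > ybest) { ybest = yY; ycode = TB_Y; }
      if (yX > ybest) { ybest = yX; ycode = TB_X; }
      Y[row + j] = (ybest <= NEG_INF_F / 2) ? NEG_INF_F : ybest;
      tbY[row + j] = ycode;
    }
    prev_lo = jlo; prev_hi = jhi;
  }

  // locate the end cell
  int ei = n, ej = m, state = TB_M;
  float endscore = NEG_INF_F;
  if (mode == 1) {
    size_t c = (size_t)n * W + m;
    endscore = M[c]; state = TB_M;
    if (X[c] > endscore) { endscore = X[c]; state = TB_X; }
    if (Y[c] > endscore) { endscore = Y[c]; state = TB_Y; }
  } else if (mode == 2) {
    // last row, then last column; first strict maximum wins
    size_t rown = (size_t)n * W;
    for (int j = 0; j <= m; ++j) {
      if (j > 0 && (j < w.rlo[n] || j > w.rhi[n])) continue;
      const float cand[3] = { M[rown + j], X[rown + j], Y[rown + j] };
      for (int s = 0; s < 3; ++s)
        if (cand[s] > endscore) { endscore = cand[s]; ei = n; ej = j; state = s; }
    }
    for (int i = 0; i < n; ++i) {
      if (w.rhi[i] != m) continue;
      size_t c = (size_t)i * W + m;
      const float cand[3] = { M[c], X[c], Y[c] };
      for (int s = 0; s < 3; ++s)
        if (cand[s] > endscore) { endscore = cand[s]; ei = i; ej = m; state = s; }
    }
  } else {
    endscore = best_local; ei = bi; ej = bj; state = TB_M;
    if (best_local <= 0.0f) {
      AlnOut out; out.score = 0.0; out.qs = out.qe = out.ts = out.te = 0;
      out.matches = out.mismatches = out.gapcols = 0; out.empty = true;
      return out;
    }
  }

  // traceback
  std::string qa, ta;
  qa.reserve(n + m); ta.reserve(n + m);
  int i = ei, j = ej;
  while (true) {
    if (mode == 1) {
      if (i == 0 && j == 0) break;
      if (i == 0) { qa.push_back('-'); ta.push_back(t[j - 1]); --j; continue; }
      if (j == 0) { qa.push_back(q[i - 1]); ta.push_back('-'); --i; continue; }
    } else {
      if (i == 0 || j == 0) break;
    }
    size_t c = (size_t)i * W + j;
    if (state == TB_M) {
      unsigned char code = tbM[c];
      qa.push_back(q[i - 1]); ta.push_back(t[j - 1]);
      --i; --j;
      if (code == TB_START) break;
      // boundary start for overlap mode: stop at the boundary next iteration
      state = code;
    } else if (state == TB_X) {
      unsigned char code = tbX[c];
      qa.push_back(q[i - 1]); ta.push_back('-');
      --i; state = code;
    } else {
      unsigned char code = tbY[c];
      qa.push_back('-'); ta.push_back(t[j - 1]);
      --j; state = code;
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(ta.begin(), ta.end());

  AlnOut out;
  out.score = (double)endscore;
  out.qs = i; out.qe = ei; out.ts = j; out.te = ej;
  out.qaln = qa; out.taln = ta;
  out.matches = out.mismatches = out.gapcols = 0;
  for (size_t k = 0; k < qa.size(); ++k) {
    char a = qa[k], b = ta[k];
    if (a == '-' || b == '-') { out.gapcols++; continue; }
    if (iupac_compatible(a, b, degen)) out.matches++;
    else out.mismatches++;
  }
  out.empty = false;
  return out;
}

List aln_to_list(const AlnOut& a) {
  int cols = a.matches + a.mismatches + a.gapcols;
  double id = cols > 0 ? 100.0 * a.matches / cols : 0.0;
  return List::create(
    _["score"] = a.score,
    _["q_start"] = a.qs + 1, _["q_end"] = a.qe,
    _["t_start"] = a.ts + 1, _["t_end"] = a.te,
    _["q_aln"] = a.qaln, _["t_aln"] = a.taln,
    _["matches"] = a.matches, _["mismatches"] = a.mismatches,
    _["gap_cols"] = a.gapcols, _["columns"] = cols,
    _["identity_pct"] = id,
    _["empty"] = a.empty);
}

}  // namespace

// [[Rcpp::export]]
List cpp_pairwise_align(std::string query, std::string target, int mode,
                        double match, double mismatch, double gap_open,
                        double gap_extend, bool degenerate, int band) {
  if (query.empty() || target.empty())
    stop("pairwise alignment requires non-empty sequences");
  AlnOut a = align_core(query, target, mode, match, mismatch, gap_open,
                        gap_extend, degenerate, band);
  return aln_to_list(a);
}

// Substitution-only identity used for OTU clustering and chimera screening:
// matches / (matches + mismatches) over the ends-free alignment, so gap
// columns (the platform's deletion-dominated noise) do not dilute the
// substitution signal that separates species.
// [[Rcpp::export]]
double cpp_cluster_identity(std::string a, std::string b, double match,
                            double mismatch, double gap_open,
                            double gap_extend, bool degenerate, int band) {
  AlnOut r = align_core(a, b, 2, match, mismatch, gap_open, gap_extend,
                        degenerate, band);
  int denom = r.matches + r.mismatches;
  return denom > 0 ? 100.0 * r.matches / denom : 0.0;
}

// Greedy abundance-ordered clustering.  `seqs` must already be sorted by
// decreasing abundance (ties: first-seen).  Membership is decided against the
// nearest existing cluster member (single-linkage within the greedy pass):
// clusters are scanned in founding order and their members in joining order,
// and the sequence joins the first cluster holding a member at
// >= threshold_pct identity, otherwise it founds a new cluster.  Comparing
// against members rather than the founder alone keeps an atypical
// high-error founder from splitting its species, while species separated by
// several times the noise rate cannot chain together.
// [[Rcpp::export]]
List cpp_greedy_cluster(CharacterVector seqs, double threshold_pct,
                        double match, double mismatch, double gap_open,
                        double gap_extend, bool degenerate,
                        int band_min, double band_frac) {
  int nseq = seqs.size();
  std::vector<std::string> ss(nseq);
  for (int i = 0; i < nseq; ++i) ss[i] = as<std::string>(seqs[i]);
  std::vector<std::vector<int>> members;  // per cluster, in joining order
  IntegerVector assign(nseq);             // 1-based cluster index
  NumericVector join_id(nseq);
  // 6-mer count vectors drive a cheap nearest-founder-first trial order, so
  // the typical sequence joins after a single alignment.  Alignment identity
  // alone decides membership.
  const int K = 6, NC = 1 << (2 * K);
  std::vector<std::vector<unsigned short>> kcnt(nseq);
  std::vector<int> ktot(nseq, 0);
  for (int i = 0; i < nseq; ++i) {
    kcnt[i].assign(NC, 0);
    int code = 0, valid = 0;
    for (size_t p = 0; p < ss[i].size(); ++p) {
      int b;
      switch (ss[i][p]) {
        case 'A': b = 0; break; case 'C': b = 1; break;
        case 'G': b = 2; break; case 'T': b = 3; break;
        default: b = -1;
      }
      if (b < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | b) & (NC - 1);
      if (++valid >= K) { kcnt[i][code]++; ktot[i]++; }
    }
  }
  auto kdist = [&](int a, int b) {
    long shared = 0;
    const unsigned short* ca = kcnt[a].data();
    const unsigned short* cb = kcnt[b].data();
    for (int c = 0; c < NC; ++c) shared += std::min(ca[c], cb[c]);
    int mn = std::min(ktot[a], ktot[b]);
    return mn > 0 ? 1.0 - (double)shared / mn : 1.0;
  };

  // Screening margin: a cluster whose founder scores far below the
  // threshold cannot plausibly hold a member within it (member-to-founder
  // spread is bounded by the within-cluster noise), so its member list is
  // only scanned when the founder lands inside the ambiguous zone.
  const double screen = threshold_pct - 5.0;
  // Membership is decided against a bounded core sample of each cluster
  // (the founder plus the earliest-joined members): early members summarise
  // the cluster centre, so scanning beyond them changes decisions only for
  // sequences that are borderline against every sampled member.
  const size_t scan_cap = 12;
  std::vector<int> order;
  for (int i = 0; i < nseq; ++i) {
    int joined = -1; double jid = 100.0;
    // rank clusters by founder 6-mer distance, ties by founding order
    order.resize(members.size());
    for (size_t c = 0; c < members.size(); ++c) order[c] = (int)c;
    std::vector<double> d(members.size());
    for (size_t c = 0; c < members.size(); ++c) d[c] = kdist(i, members[c][0]);
    std::stable_sort(order.begin(), order.end(),
                     [&](int a, int b) { return d[a] < d[b]; });
    for (size_t oc = 0; oc < order.size() && joined < 0; ++oc) {
      size_t c = (size_t)order[oc];
      size_t lim = std::min(members[c].size(), scan_cap);
      for (size_t k = 0; k < lim; ++k) {
        const std::string& cs = ss[members[c][k]];
        int mx = (int)std::max(cs.size(), ss[i].size());
        int df = (int)std::abs((long)cs.size() - (long)ss[i].size());
        int band = std::max(band_min, (int)(band_frac * mx) + df);
        double id = cpp_cluster_identity(ss[i], cs, match, mismatch, gap_open,
                                         gap_extend, degenerate, band);
        if (id >= threshold_pct) { joined = (int)c; jid = id; break; }
        if (k == 0 && id < screen) break;  // founder screen
      }
    }
    if (joined >= 0) {
      members[joined].push_back(i);
      assign[i] = joined + 1;
      join_id[i] = jid;
    } else {
      members.push_back(std::vector<int>(1, i));
      assign[i] = (int)members.size();
      join_id[i] = 100.0;
    }
  }
  IntegerVector founder(members.size());
  for (size_t c = 0; c < members.size(); ++c) founder[c] = members[c][0] + 1;
  return List::create(_["assignment"] = assign, _["centroids"] = founder,
                      _["best_identity"] = join_id);
}
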
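#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
#include <algorithm>
using namespace Rcpp;

// Affine-gap pairwise alignment of each pattern against one subject.
//
// free_ends = true  -> overlap alignment: end gaps on either sequence are
//                      unpenalized, score is max over the last row/column,
//                      traceback stops at the first row/column.
// free_ends = false -> global alignment over the full sequences.
//
// A gap of length L costs gap_open + L * gap_ext (Biostrings convention).
// Traceback tie-break is fixed: diagonal, then up (consume pattern), then
// left (consume subject), so results are deterministic.
//
// Scores are integer-valued (the scoring parameters are small integers);
// integer DP is what keeps pipeline-scale alignment fast.

static const int NEG = -1000000000; // safe -inf: never reached by real paths

// [[Rcpp::export(name = ".align_pairwise_cpp")]]
List align_pairwise_cpp(CharacterVector patterns, std::string subject,
                        int match, int mismatch,
                        int gap_open, int gap_ext,
                        bool free_ends, bool keep_strings) {
  const int n = (int) subject.size();
  if (n == 0) stop("empty subject sequence");
  List out(patterns.size());

  std::vector<int> H, E, F; // (m+1) x (n+1), row-major
  const int open_cost = gap_open + gap_ext;

  for (int p = 0; p < patterns.size(); ++p) {
    std::string pat = as<std::string>(patterns[p]);
    const int m = (int) pat.size();
    if (m == 0) stop("empty pattern sequence");
    const size_t sz = (size_t)(m + 1) * (n + 1);
    H.assign(sz, 0); E.assign(sz, NEG); F.assign(sz, NEG);
    #define IX(i, j) ((size_t)(i) * (n + 1) + (j))

    if (!free_ends) {
      for (int j = 1; j <= n; ++j) {
        H[IX(0, j)] = -(gap_open + gap_ext * j); E[IX(0, j)] = H[IX(0, j)];
      }
      for (int i = 1; i <= m; ++i) {
        H[IX(i, 0)] = -(gap_open + gap_ext * i); F[IX(i, 0)] = H[IX(i, 0)];
      }
    }

    for (int i = 1; i <= m; ++i) {
      const char pc = pat[i - 1];
      int *Hr = &H[IX(i, 0)], *Hp = &H[IX(i - 1, 0)];
      int *Er = &E[IX(i, 0)];
      int *Fr = &F[IX(i, 0)], *Fp = &F[IX(i - 1, 0)];
      for (int j = 1; j <= n; ++j) {
        const int e = std::max(Hr[j - 1] - open_cost, Er[j - 1] - gap_ext);
        const int f = std::max(Hp[j] - open_cost, Fp[j] - gap_ext);
        const int s = (pc == subject[j - 1] && pc != 'N') ? match : mismatch;
        const int d = Hp[j - 1] + s;
        int h = d > f ? d : f; if (e > h) h = e;
        Er[j] = e; Fr[j] = f; Hr[j] = h;
      }
    }

    // end cell: global ends at (m, n); overlap scans the last row/column
    int bi = m, bj = n;
    if (free_ends) {
      int best = NEG;
      for (int i = 1; i <= m; ++i)
        if (H[IX(i, n)] > best) { best = H[IX(i, n)]; bi = i; bj = n; }
      for (int j = 1; j <= n; ++j)
        if (H[IX(m, j)] > best) { best = H[IX(m, j)]; bi = m; bj = j; }
    }
    const int score = H[IX(bi, bj)];

    // traceback from (bi, bj); state 0 = H, 1 = F (up), 2 = E (left)
    std::vector<int> ppos, spos;  // matched columns (1-based)
    std::string gp, gs;           // gapped strings, built reversed
    int i = bi, j = bj, state = 0;
    int nmatch = 0, nmismatch = 0, ncol = 0;
    while (true) {
      if (free_ends && (i == 0 || j == 0)) break;
      if (!free_ends && i == 0 && j == 0) break;
      if (i == 0) { // global boundary: consume subject
        gp.push_back('-'); gs.push_back(subject[j - 1]); --j; ++ncol; continue;
      }
      if (j == 0) {
        gp.push_back(pat[i - 1]); gs.push_back('-'); --i; ++ncol; continue;
      }
      if (state == 0) {
        const char pc = pat[i - 1], sc = subject[j - 1];
        const int s = (pc == sc && pc != 'N') ? match : mismatch;
        if (H[IX(i, j)] == H[IX(i - 1, j - 1)] + s) {
          ppos.push_back(i); spos.push_back(j);
          if (pc == sc && pc != 'N') ++nmatch; else ++nmismatch;
          gp.push_back(pc); gs.push_back(sc);
          --i; --j; ++ncol; continue;
        }
        if (H[IX(i, j)] == F[IX(i, j)]) { state = 1; continue; }
        if (H[IX(i, j)] == E[IX(i, j)]) { state = 2; continue; }
        stop("traceback failure");
      } else if (state == 1) { // gap in subject, consume pattern
        gp.push_back(pat[i - 1]); gs.push_back('-'); ++ncol;
        const bool opened = (F[IX(i, j)] == H[IX(i - 1, j)] - open_cost);
        --i; state = opened ? 0 : 1; continue;
      } else {                 // gap in pattern, consume subject
        gp.push_back('-'); gs.push_back(subject[j - 1]); ++ncol;
        const bool opened = (E[IX(i, j)] == H[IX(i, j - 1)] - open_cost);
        --j; state = opened ? 0 : 2; continue;
      }
    }
    const int pstart = i + 1, sstart = j + 1;
    std::reverse(ppos.begin(), ppos.end());
    std::reverse(spos.begin(), spos.end());

    List res = List::create(
      _["score"] = (double) score,
      _["pstart"] = pstart, _["pend"] = bi,
      _["sstart"] = sstart, _["send"] = bj,
      _["ppos"] = wrap(ppos), _["spos"] = wrap(spos),
      _["nmatch"] = nmatch, _["nmismatch"] = nmismatch,
      _["ncol"] = ncol);
    if (keep_strings) {
      std::reverse(gp.begin(), gp.end());
      std::reverse(gs.begin(), gs.end());
      res["gapped_pattern"] = gp;
      res["gapped_subject"] = gs;
    }
    out[p] = res;
    #undef IX
  }
  return out;
}

// Columnar batch wrapper for pipeline-scale use: one overlap alignment per
// pattern, scalar fields returned as vectors (avoids per-hit R extraction).
// [[Rcpp::export(name = ".align_batch_cpp")]]
List align_batch_cpp(CharacterVector patterns, std::string subject,
                     int match, int mismatch, int gap_open, int gap_ext) {
  List full = align_pairwise_cpp(patterns, subject, match, mismatch,
                                 gap_open, gap_ext, true, false);
  const int np = full.size();
  NumericVector score(np);
  IntegerVector pstart(np), pend(np), sstart(np), send(np),
                nmatch(np), nmismatch(np), ncol(np);
  List ppos(np), spos(np);
  for (int i = 0; i < np; ++i) {
    List r = full[i];
    score[i] = as<double>(r["score"]);
    pstart[i] = as<int>(r["pstart"]); pend[i] = as<int>(r["pend"]);
    sstart[i] = as<int>(r["sstart"]); send[i] = as<int>(r["send"]);
    nmatch[i] = as<int>(r["nmatch"]); nmismatch[i] = as<int>(r["nmismatch"]);
    ncol[i] = as<int>(r["ncol"]);
    ppos[i] = r["ppos"]; spos[i] = r["spos"];
  }
  return List::create(_["score"] = score, _["pstart"] = pstart,
                      _["pend"] = pend, _["sstart"] = sstart,
                      _["send"] = send, _["nmatch"] = nmatch,
                      _["nmismatch"] = nmismatch, _["ncol"] = ncol,
                      _["ppos"] = ppos, _["spos"] = spos);
}
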
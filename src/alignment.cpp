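#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment with linear gap penalties.
//
// Determinism contract: among cells attaining the maximal score, the
// alignment whose subject start (then query start) is smallest is returned;
// traceback inside a cell prefers diagonal over up (gap in subject) over
// left (gap in query). Any base outside {A,C,G,T} (e.g. N) never matches.

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': case 'U': case 'u': return 3;
    default: return -1;
  }
}

struct TraceResult {
  int qs, qe, ss, se;      // 1-based inclusive
  int matches, mismatches, gaps;
};

static TraceResult traceback(const std::vector<int> &H,
                             const std::string &a, const std::string &b,
                             int m, int n, int ei, int ej,
                             int match, int mismatch, int gap) {
  TraceResult tr = {0, 0, 0, 0, 0, 0, 0};
  int i = ei, j = ej;
  tr.qe = ei;
  tr.se = ej;
  while (i > 0 && j > 0 && H[i * (n + 1) + j] > 0) {
    int h = H[i * (n + 1) + j];
    int ca = base_code(a[i - 1]), cb = base_code(b[j - 1]);
    bool is_match = (ca >= 0 && ca == cb);
    int sub = is_match ? match : mismatch;
    if (H[(i - 1) * (n + 1) + (j - 1)] + sub == h) {
      if (is_match) tr.matches++; else tr.mismatches++;
      i--; j--;
    } else if (H[(i - 1) * (n + 1) + j] + gap == h) {
      tr.gaps++;
      i--;
    } else {
      tr.gaps++;
      j--;
    }
  }
  tr.qs = i + 1;
  tr.ss = j + 1;
  return tr;
}

// [[Rcpp::export(name = ".sw_align")]]
List sw_align(std::string query, std::string subject,
              int match = 1, int mismatch = -2, int gap = -3) {
  int m = (int) query.size(), n = (int) subject.size();
  std::vector<int> H((m + 1) * (n + 1), 0);
  int best = 0;
  for (int i = 1; i <= m; i++) {
    int ca = base_code(query[i - 1]);
    for (int j = 1; j <= n; j++) {
      int cb = base_code(subject[j - 1]);
      int sub = (ca >= 0 && ca == cb) ? match : mismatch;
      int v = H[(i - 1) * (n + 1) + (j - 1)] + sub;
      int up = H[(i - 1) * (n + 1) + j] + gap;
      int lf = H[i * (n + 1) + (j - 1)] + gap;
      if (up > v) v = up;
      if (lf > v) v = lf;
      if (v < 0) v = 0;
      H[i * (n + 1) + j] = v;
      if (v > best) best = v;
    }
  }
  if (best == 0) {
    return List::create(_["score"] = 0,
                        _["query_start"] = 0, _["query_end"] = 0,
                        _["subject_start"] = 0, _["subject_end"] = 0,
                        _["matches"] = 0, _["mismatches"] = 0, _["gaps"] = 0);
  }
  // all maximal cells, traced; keep the smallest (subject_start, query_start)
  TraceResult bestTr = {0, 0, 0, 0, 0, 0, 0};
  bool found = false;
  for (int i = 1; i <= m; i++) {
    for (int j = 1; j <= n; j++) {
      if (H[i * (n + 1) + j] == best) {
        TraceResult tr = traceback(H, query, subject, m, n, i, j,
                                   match, mismatch, gap);
        if (!found || tr.ss < bestTr.ss ||
            (tr.ss == bestTr.ss && tr.qs < bestTr.qs)) {
          bestTr = tr;
          found = true;
        }
      }
    }
  }
  return List::create(_["score"] = best,
                      _["query_start"] = bestTr.qs,
                      _["query_end"] = bestTr.qe,
                      _["subject_start"] = bestTr.ss,
                      _["subject_end"] = bestTr.se,
                      _["matches"] = bestTr.matches,
                      _["mismatches"] = bestTr.mismatches,
                      _["gaps"] = bestTr.gaps);
}
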
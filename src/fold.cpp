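#include <Rcpp.h>
using namespace Rcpp;

// Weighted Nussinov folding: maximise the sum of pair weights
// (GC/CG = 3, AU/UA = 2, GU/UG = 1) over pseudoknot-free structures with a
// minimum hairpin loop of `min_loop` unpaired bases. Deterministic
// traceback: for interval (i,j) the options are tried in the order
//   pair (i,j)  >  i unpaired  >  j unpaired  >  bifurcation at smallest k
// so dot-bracket strings are byte-for-byte reproducible.

static inline int fold_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': case 'U': case 'u': return 3;
    default: return -1;
  }
}

static inline int pair_weight(int a, int b) {
  if (a < 0 || b < 0) return 0;
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return 3;  // G:C
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return 2;  // A:U
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return 1;  // G:U
  return 0;
}

// [[Rcpp::export(name = ".nussinov_fold")]]
List nussinov_fold(std::string seq, int min_loop = 3) {
  int n = (int) seq.size();
  std::vector<int> code(n);
  for (int i = 0; i < n; i++) {
    code[i] = fold_code(seq[i]);
    if (code[i] < 0) stop("invalid base '%s' at position %d",
                          std::string(1, seq[i]).c_str(), i + 1);
  }
  if (n == 0)
    return List::create(_["partner"] = IntegerVector(0), _["score"] = 0);

  std::vector<int> N((size_t) n * n, 0);
  // fill by increasing span
  for (int span = min_loop + 1; span < n; span++) {
    for (int i = 0; i + span < n; i++) {
      int j = i + span;
      int bestv = 0;
      int w = pair_weight(code[i], code[j]);
      if (w > 0 && j - i > min_loop) {
        int v = w + (i + 1 <= j - 1 ? N[(size_t)(i + 1) * n + (j - 1)] : 0);
        if (v > bestv) bestv = v;
      }
      int v = N[(size_t)(i + 1) * n + j];           // i unpaired
      if (v > bestv) bestv = v;
      v = N[(size_t) i * n + (j - 1)];              // j unpaired
      if (v > bestv) bestv = v;
      for (int k = i + 1; k <= j - 2; k++) {        // bifurcation
        v = N[(size_t) i * n + k] + N[(size_t)(k + 1) * n + j];
        if (v > bestv) bestv = v;
      }
      N[(size_t) i * n + j] = bestv;
    }
  }

  IntegerVector partner(n, 0);  // 1-based partner, 0 = unpaired
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j) continue;
    int target = N[(size_t) i * n + j];
    if (target == 0) continue;
    int w = pair_weight(code[i], code[j]);
    if (w > 0 && j - i > min_loop &&
        w + (i + 1 <= j - 1 ? N[(size_t)(i + 1) * n + (j - 1)] : 0) == target) {
      partner[i] = j + 1;
      partner[j] = i + 1;
      stack.push_back(std::make_pair(i + 1, j - 1));
      continue;
    }
    if (N[(size_t)(i + 1) * n + j] == target) {
      stack.push_back(std::make_pair(i + 1, j));
      continue;
    }
    if (N[(size_t) i * n + (j - 1)] == target) {
      stack.push_back(std::make_pair(i, j - 1));
      continue;
    }
    for (int k = i + 1; k <= j - 2; k++) {
      if (N[(size_t) i * n + k] + N[(size_t)(k + 1) * n + j] == target) {
        stack.push_back(std::make_pair(k + 1, j));
        stack.push_back(std::make_pair(i, k));
        break;
      }
    }
  }
  return List::create(_["partner"] = partner,
                      _["score"] = N[(size_t) 0 * n + (n - 1)]);
}
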
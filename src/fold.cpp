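#include <Rcpp.h>
using namespace Rcpp;

// Canonical pairs over {A,C,G,U}: Watson-Crick plus the G:U wobble.
static inline bool can_pair(char a, char b) {
  switch (a) {
  case 'A': return b == 'U';
  case 'U': return b == 'A' || b == 'G';
  case 'G': return b == 'C' || b == 'U';
  case 'C': return b == 'G';
  default:  return false;
  }
}

// Base-pair maximization over non-crossing structures (Nussinov-style DP)
// with a minimum hairpin loop of `min_loop` unpaired bases. Traceback is
// deterministic: leave j unpaired when that already attains the optimum,
// otherwise pair j with the smallest admissible k.
// [[Rcpp::export(name = ".fold_maxpair_cpp")]]
List fold_maxpair_cpp(std::string seq, int min_loop) {
  const int n = (int) seq.size();
  if (n == 0) return List::create(_["structure"] = "", _["pairs"] = 0);

  std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = M[i][j - 1];                       // j unpaired
      for (int k = i; k <= j - min_loop - 1; ++k) { // j paired with k
        if (!can_pair(seq[k], seq[j])) continue;
        int v = 1 + (k > i ? M[i][k - 1] : 0) + M[k + 1][j - 1];
        if (v > best) best = v;
      }
      M[i][j] = best;
    }
  }

  std::string db(n, '.');
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i < min_loop + 1) continue;
    if (M[i][j] == M[i][j - 1]) {
      stack.push_back(std::make_pair(i, j - 1));
      continue;
    }
    for (int k = i; k <= j - min_loop - 1; ++k) {
      if (!can_pair(seq[k], seq[j])) continue;
      int v = 1 + (k > i ? M[i][k - 1] : 0) + M[k + 1][j - 1];
      if (v == M[i][j]) {
        db[k] = '(';
        db[j] = ')';
        if (k > i) stack.push_back(std::make_pair(i, k - 1));
        stack.push_back(std::make_pair(k + 1, j - 1));
        break;
      }
    }
  }

  return List::create(_["structure"] = db, _["pairs"] = M[0][n - 1]);
}

// Minimum Hamming distance of `read` to any same-length substring of any
// reference (references already expanded to both strands by the caller).
// Early exit once a hit at or below max_mm is found.
// [[Rcpp::export(name = ".structural_hit_cpp")]]
LogicalVector structural_hit_cpp(CharacterVector reads, CharacterVector refs,
                                 int max_mm) {
  const int nr = reads.size();
  LogicalVector hit(nr, false);
  std::vector<std::string> R(refs.size());
  for (int s = 0; s < refs.size(); ++s) R[s] = as<std::string>(refs[s]);

  for (int q = 0; q < nr; ++q) {
    std::string rd = as<std::string>(reads[q]);
    const int L = (int) rd.size();
    bool found = false;
    for (size_t s = 0; s < R.size() && !found; ++s) {
      const std::string &ref = R[s];
      if ((int) ref.size() < L) continue;
      for (int off = 0; off + L <= (int) ref.size() && !found; ++off) {
        int mm = 0;
        for (int p = 0; p < L; ++p) {
          if (rd[p] != ref[off + p] && ++mm > max_mm) break;
        }
        if (mm <= max_mm) found = true;
      }
    }
    hit[q] = found;
  }
  return hit;
}

// 5'-anchored substitution counts: queries x references matrix, counting
// mismatches over the overlap min(len_q, len_r) from the 5' end.
// [[Rcpp::export(name = ".prefix_mismatch_cpp")]]
IntegerMatrix prefix_mismatch_cpp(CharacterVector queries,
                                  CharacterVector refs) {
  const int nq = queries.size(), nr = refs.size();
  std::vector<std::string> Q(nq), R(nr);
  for (int i = 0; i < nq; ++i) Q[i] = as<std::string>(queries[i]);
  for (int j = 0; j < nr; ++j) R[j] = as<std::string>(refs[j]);
  IntegerMatrix out(nq, nr);
  for (int i = 0; i < nq; ++i) {
    for (int j = 0; j < nr; ++j) {
      int L = std::min(Q[i].size(), R[j].size());
      int mm = 0;
      for (int p = 0; p < L; ++p)
        if (Q[i][p] != R[j][p]) ++mm;
      out(i, j) = mm;
    }
  }
  return out;
}
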
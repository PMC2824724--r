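#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Base-pair maximization fold (Nussinov-style DP) over RNA with
// Watson-Crick + G.U wobble pairs and a minimum hairpin loop of `min_loop`
// unpaired bases. Traceback is deterministic: when pairing the 3' base of an
// interval ties the unpaired option, the pairing is taken, with the 5'-most
// partner among ties.

static inline bool can_pair(char a, char b, bool allow_gu) {
  switch (a) {
  case 'A': return b == 'U';
  case 'U': return b == 'A' || (allow_gu && b == 'G');
  case 'G': return b == 'C' || (allow_gu && b == 'U');
  case 'C': return b == 'G';
  default: return false;
  }
}

// [[Rcpp::export(name = ".nussinov_fold")]]
List nussinov_fold(std::string seq, int min_loop = 3, bool allow_gu = true) {
  int n = seq.size();
  for (int i = 0; i < n; ++i) {
    char c = seq[i];
    if (c != 'A' && c != 'C' && c != 'G' && c != 'U' && c != 'N')
      stop("sequence contains characters outside {A,C,G,U,N}");
  }
  std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = M[i][j - 1];
      for (int k = i; k <= j - min_loop - 1; ++k) {
        if (!can_pair(seq[k], seq[j], allow_gu)) continue;
        int v = 1 + (k > i ? M[i][k - 1] : 0) + (k + 1 <= j - 1 ? M[k + 1][j - 1] : 0);
        if (v > best) best = v;
      }
      M[i][j] = best;
    }
  }
  IntegerVector pair(n, 0);
  // iterative traceback over interval stack
  std::vector<std::pair<int, int> > stack;
  if (n > 0) stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i < min_loop + 1) continue;
    int best = M[i][j];
    int chosen = -1;
    for (int k = i; k <= j - min_loop - 1; ++k) {
      if (!can_pair(seq[k], seq[j], allow_gu)) continue;
      int v = 1 + (k > i ? M[i][k - 1] : 0) + (k + 1 <= j - 1 ? M[k + 1][j - 1] : 0);
      if (v == best) { chosen = k; break; }  // 5'-most partner, pairing preferred
    }
    if (chosen < 0) {
      stack.push_back(std::make_pair(i, j - 1));
    } else {
      pair[chosen] = j + 1;  // 1-based
      pair[j] = chosen + 1;
      if (chosen > i) stack.push_back(std::make_pair(i, chosen - 1));
      if (chosen + 1 <= j - 1) stack.push_back(std::make_pair(chosen + 1, j - 1));
    }
  }
  std::string db(n, '.');
  int np = 0;
  for (int i = 0; i < n; ++i) {
    if (pair[i] > i + 1) { db[i] = '('; db[pair[i] - 1] = ')'; ++np; }
  }
  return List::create(_["db"] = db, _["pairs"] = pair, _["n_pairs"] = np);
}
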
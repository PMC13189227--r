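#include <Rcpp.h>
using namespace Rcpp;

// Base-pair test on RNA alphabet: A-U, C-G, G-U (wobble).
static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'C' && b == 'G') || (a == 'G' && b == 'C') ||
         (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// Pairing-maximization (Nussinov-style) fold with a minimum hairpin loop of
// `min_loop` unpaired bases. Deterministic traceback: an unpaired 5' base is
// preferred when optimal, otherwise the smallest pairing partner. Returns the
// dot-bracket string and the pair count.
// [[Rcpp::export(name = ".nussinov_fold")]]
List nussinov_fold(std::string seq, int min_loop = 3) {
  int n = seq.size();
  std::string db(n, '.');
  if (n == 0) return List::create(_["dotbracket"] = db, _["n_pairs"] = 0);

  std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = M[i + 1][j]; // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!can_pair(seq[i], seq[k])) continue;
        int inner = (k - i > min_loop + 1) ? M[i + 1][k - 1] : 0;
        int right = (k < j) ? M[k + 1][j] : 0;
        int cand = 1 + inner + right;
        if (cand > best) best = cand;
      }
      M[i][j] = best;
    }
  }

  // traceback over subproblem stack
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  int n_pairs = 0;
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i <= min_loop) continue;
    if (M[i][j] == M[i + 1][j]) {
      stack.push_back(std::make_pair(i + 1, j));
      continue;
    }
    for (int k = i + min_loop + 1; k <= j; ++k) {
      if (!can_pair(seq[i], seq[k])) continue;
      int inner = (k - i > min_loop + 1) ? M[i + 1][k - 1] : 0;
      int right = (k < j) ? M[k + 1][j] : 0;
      if (1 + inner + right == M[i][j]) {
        db[i] = '(';
        db[k] = ')';
        ++n_pairs;
        if (k - i > min_loop + 1) stack.push_back(std::make_pair(i + 1, k - 1));
        if (k < j) stack.push_back(std::make_pair(k + 1, j));
        break;
      }
    }
  }
  return List::create(_["dotbracket"] = db, _["n_pairs"] = n_pairs);
}

// Intermolecular complementarity maximization between two strands: pairs
// (i on A ascending, j on B descending) without crossings, i.e. an alignment
// of A against the reverse of B scoring complementary (incl. wobble) matches.
// Returns 0-based paired positions in each strand's own 5'->3' coordinates.
// [[Rcpp::export(name = ".duplex_hybridize")]]
List duplex_hybridize(std::string a, std::string b) {
  int n = a.size(), m = b.size();
  std::string brev(b.rbegin(), b.rend());
  std::vector<std::vector<int> > M(n + 1, std::vector<int>(m + 1, 0));
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int best = M[i - 1][j] > M[i][j - 1] ? M[i - 1][j] : M[i][j - 1];
      if (can_pair(a[i - 1], brev[j - 1]) && M[i - 1][j - 1] + 1 > best)
        best = M[i - 1][j - 1] + 1;
      M[i][j] = best;
    }
  }
  std::vector<int> pa, pb;
  int i = n, j = m;
  while (i > 0 && j > 0) {
    if (can_pair(a[i - 1], brev[j - 1]) && M[i][j] == M[i - 1][j - 1] + 1) {
      pa.push_back(i - 1);
      pb.push_back(m - j); // back to B's own orientation
      --i;
      --j;
    } else if (M[i - 1][j] >= M[i][j - 1]) {
      --i;
    } else {
      --j;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["pos_a"] = wrap(pa), _["pos_b"] = wrap(pb));
}
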
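#include <Rcpp.h>
using namespace Rcpp;

// Base-pair maximization folding (Nussinov-style) with simple stacking
// weights: G:C = 3, A:U = 2, G:U = 1, minimum hairpin loop of 3 unpaired
// bases.  Reported "mfe" is the negated pair score, a pseudo-energy used
// only by the dependency-free testing backend.  Traceback is deterministic
// (leave-j-unpaired preferred, then the smallest bifurcation point).

static int pair_w(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return 2;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return 1;
  return 0;
}

// [[Rcpp::export(name = "nussinov_fold_cpp")]]
List nussinov_fold(std::string seq) {
  const int n = seq.size();
  const int minloop = 3;
  std::vector<std::vector<int> > N(n, std::vector<int>(n, 0));
  for (int span = minloop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = N[i][j - 1];  // j unpaired
      for (int k = i; k <= j - minloop - 1; ++k) {
        int w = pair_w(seq[k], seq[j]);
        if (w == 0) continue;
        int s = w + (k > i ? N[i][k - 1] : 0) + N[k + 1][j - 1];
        if (s > best) best = s;
      }
      N[i][j] = best;
    }
  }
  // deterministic traceback
  std::string db(n, '.');
  std::vector<std::pair<int, int> > stack;
  if (n > 0) stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i <= minloop) continue;
    if (N[i][j] == N[i][j - 1]) {
      stack.push_back(std::make_pair(i, j - 1));
      continue;
    }
    for (int k = i; k <= j - minloop - 1; ++k) {
      int w = pair_w(seq[k], seq[j]);
      if (w == 0) continue;
      int s = w + (k > i ? N[i][k - 1] : 0) + N[k + 1][j - 1];
      if (s == N[i][j]) {
        db[k] = '(';
        db[j] = ')';
        if (k > i) stack.push_back(std::make_pair(i, k - 1));
        stack.push_back(std::make_pair(k + 1, j - 1));
        break;
      }
    }
  }
  double score = (n > 0) ? N[0][n - 1] : 0;
  return List::create(_["structure"] = db, _["mfe"] = -score);
}
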
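#include <Rcpp.h>
using namespace Rcpp;

// Levenshtein DP with full backtrace. Tie-break during backtrace prefers the
// diagonal move, which places indels at the leftmost equivalent position
// (e.g. a deletion in a homopolymer is reported at the first base of the run).
// Also counts the number of distinct optimal alignments (capped) so callers
// can flag ambiguous decompositions.

// [[Rcpp::export]]
List cpp_edit_script(std::string parent, std::string variant) {
  const int n = parent.size(), m = variant.size();
  NumericMatrix d(n + 1, m + 1);
  NumericMatrix cnt(n + 1, m + 1);
  const double CAP = 1e9;
  for (int i = 0; i <= n; ++i) { d(i, 0) = i; cnt(i, 0) = 1; }
  for (int j = 0; j <= m; ++j) { d(0, j) = j; cnt(0, j) = 1; }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double sub = d(i - 1, j - 1) + ((parent[i - 1] == variant[j - 1] && parent[i - 1] != 'N') ? 0 : 1);
      double del = d(i - 1, j) + 1;
      double ins = d(i, j - 1) + 1;
      double best = std::min(sub, std::min(del, ins));
      d(i, j) = best;
      double c = 0;
      if (sub == best) c += cnt(i - 1, j - 1);
      if (del == best) c += cnt(i - 1, j);
      if (ins == best) c += cnt(i, j - 1);
      cnt(i, j) = std::min(c, CAP);
    }
  }
  // backtrace, preferring diagonal then deletion then insertion
  std::vector<std::string> op;
  std::vector<int> pos;
  std::vector<std::string> base;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        d(i, j) == d(i - 1, j - 1) + ((parent[i - 1] == variant[j - 1] && parent[i - 1] != 'N') ? 0 : 1)) {
      if (!(parent[i - 1] == variant[j - 1] && parent[i - 1] != 'N')) {
        op.push_back("substitution");
        pos.push_back(i);
        base.push_back(std::string(1, variant[j - 1]));
      }
      --i; --j;
    } else if (i > 0 && d(i, j) == d(i - 1, j) + 1) {
      op.push_back("deletion");
      pos.push_back(i);
      base.push_back("-");
      --i;
    } else {
      op.push_back("insertion");
      pos.push_back(i);  // insertion after parent position i (0..n)
      base.push_back(std::string(1, variant[j - 1]));
      --j;
    }
  }
  std::reverse(op.begin(), op.end());
  std::reverse(pos.begin(), pos.end());
  std::reverse(base.begin(), base.end());
  return List::create(
    _["op"] = wrap(op), _["pos"] = wrap(pos), _["base"] = wrap(base),
    _["distance"] = d(n, m),
    _["ambiguous"] = cnt(n, m) > 1.5);
}

// Plain Levenshtein distance with early-abandon band, for bulk filtering.
// [[Rcpp::export]]
IntegerVector cpp_lv_distance(std::string query, CharacterVector targets,
                              int max_dist) {
  const int n = query.size();
  IntegerVector out(targets.size());
  std::vector<int> prev(n + 1), cur(n + 1);
  for (int t = 0; t < targets.size(); ++t) {
    std::string s = as<std::string>(targets[t]);
    const int m = s.size();
    if (std::abs(m - n) > max_dist) { out[t] = max_dist + 1; continue; }
    for (int i = 0; i <= n; ++i) prev[i] = i;
    int best = 0;
    for (int j = 1; j <= m; ++j) {
      cur[0] = j;
      best = cur[0];
      for (int i = 1; i <= n; ++i) {
        int sub = prev[i - 1] + ((query[i - 1] == s[j - 1] && query[i - 1] != 'N') ? 0 : 1);
        cur[i] = std::min(sub, std::min(prev[i] + 1, cur[i - 1] + 1));
        if (cur[i] < best) best = cur[i];
      }
      if (best > max_dist) break;
      std::swap(prev, cur);
    }
    out[t] = best > max_dist ? max_dist + 1 : prev[n];
  }
  return out;
}
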
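#include <Rcpp.h>
using namespace Rcpp;

// Levenshtein DP (unit costs) with a deterministic backtrace decomposing the
// distance into substitution / insertion / deletion counts. Tie-break order:
// match > substitution > deletion > insertion. Insertions are characters
// present in `read` but not `ref`; deletions are reference characters absent
// from the read.

// [[Rcpp::export(name = ".edit_ops_cpp")]]
List edit_ops_cpp(std::string ref, std::string read) {
  const int m = ref.size(), n = read.size();
  IntegerMatrix D(m + 1, n + 1);
  for (int i = 0; i <= m; ++i) D(i, 0) = i;
  for (int j = 0; j <= n; ++j) D(0, j) = j;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int diag = D(i - 1, j - 1) + (ref[i - 1] != read[j - 1]);
      int del = D(i - 1, j) + 1;
      int ins = D(i, j - 1) + 1;
      int best = diag < del ? diag : del;
      D(i, j) = best < ins ? best : ins;
    }
  }
  int i = m, j = n, n_sub = 0, n_ins = 0, n_del = 0;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 && ref[i - 1] == read[j - 1] &&
        D(i, j) == D(i - 1, j - 1)) {
      --i; --j;                       // match
    } else if (i > 0 && j > 0 && D(i, j) == D(i - 1, j - 1) + 1) {
      ++n_sub; --i; --j;              // substitution
    } else if (i > 0 && D(i, j) == D(i - 1, j) + 1) {
      ++n_del; --i;                   // deletion
    } else {
      ++n_ins; --j;                   // insertion
    }
  }
  return List::create(_["distance"] = D(m, n), _["n_sub"] = n_sub,
                      _["n_ins"] = n_ins, _["n_del"] = n_del);
}
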
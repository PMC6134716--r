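// Brute-force reference routines used only by the test suite and the
// acceptance checks: a textbook unbanded Levenshtein DP with no band, no
// early termination and no filtering. Deliberately shares no code with
// engine.cpp so it can serve as an independent cross-check.

#include <Rcpp.h>
#include <string>
#include <vector>

using namespace Rcpp;

static int naive_edit(const std::string& a, const std::string& b) {
  int m = (int)a.size(), n = (int)b.size();
  std::vector<int> prev(n + 1), cur(n + 1);
  for (int j = 0; j <= n; ++j) prev[j] = j;
  for (int i = 1; i <= m; ++i) {
    cur[0] = i;
    for (int j = 1; j <= n; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      cur[j] = sub < del ? (sub < ins ? sub : ins) : (del < ins ? del : ins);
    }
    std::swap(prev, cur);
  }
  return prev[n];
}

// [[Rcpp::export]]
int cpp_naive_edit(std::string a, std::string b) { return naive_edit(a, b); }

// [[Rcpp::export]]
IntegerMatrix cpp_naive_edit_matrix(CharacterVector seqs) {
  int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  IntegerMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int d = naive_edit(s[i], s[j]);
      out(i, j) = d;
      out(j, i) = d;
    }
  }
  return out;
}
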
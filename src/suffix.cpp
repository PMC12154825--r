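#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Suffix array by prefix doubling. `text` is a vector of integer codes with
// the terminator being the unique smallest code. Returns 0-based positions.
// O(n log^2 n); adequate for desk-scale references (a few Mb).
// [[Rcpp::export]]
IntegerVector sa_prefix_doubling(IntegerVector text) {
  const int n = text.size();
  std::vector<int> sa(n), rnk(n), tmp(n);
  for (int i = 0; i < n; ++i) { sa[i] = i; rnk[i] = text[i]; }
  for (int k = 1; ; k <<= 1) {
    auto cmp = [&](int a, int b) {
      if (rnk[a] != rnk[b]) return rnk[a] < rnk[b];
      int ra = a + k < n ? rnk[a + k] : -1;
      int rb = b + k < n ? rnk[b + k] : -1;
      return ra < rb;
    };
    std::sort(sa.begin(), sa.end(), cmp);
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; ++i)
      tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
    rnk = tmp;
    if (rnk[sa[n - 1]] == n - 1) break;
  }
  return wrap(sa);
}

// Kasai's LCP construction: lcp[i] = longest common prefix of the suffixes
// at sa[i-1] and sa[i]; lcp[0] = 0. Linear time.
// [[Rcpp::export]]
IntegerVector lcp_kasai(IntegerVector text, IntegerVector sa) {
  const int n = text.size();
  std::vector<int> rnk(n);
  IntegerVector lcp(n);
  for (int i = 0; i < n; ++i) rnk[sa[i]] = i;
  int h = 0;
  for (int i = 0; i < n; ++i) {
    if (rnk[i] > 0) {
      int j = sa[rnk[i] - 1];
      while (i + h < n && j + h < n && text[i + h] == text[j + h]) ++h;
      lcp[rnk[i]] = h;
      if (h > 0) --h;
    } else {
      h = 0;
    }
  }
  return lcp;
}
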
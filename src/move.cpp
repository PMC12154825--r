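#include <Rcpp.h>
#include <climits>
#include <vector>
using namespace Rcpp;

// Per-run repositioning thresholds from the LCP array.
//
// For a run of character x and a query character c != x, the threshold is the
// within-run offset such that offsets j < threshold reposition up (towards the
// nearest preceding occurrence of c) and offsets j >= threshold reposition
// down. It is derived from the flat position of the first minimum of LCP
// strictly between the nearest occurrence of c above the run and the nearest
// occurrence below, clamped to [0, run length]. Runs with no occurrence of c
// above get 0 (always down); none below get the run length (always up).
//
// run_chars: integer codes, 0 = terminator, 1..4 = A,C,G,T
// Returns an r x 4 matrix (columns A,C,G,T); entries for the run's own
// character are NA.
// [[Rcpp::export]]
IntegerMatrix thresholds_from_lcp(IntegerVector run_chars,
                                  IntegerVector run_starts,
                                  IntegerVector run_lens,
                                  IntegerVector lcp) {
  const int r = run_chars.size();
  IntegerMatrix th(r, 4);
  for (int c = 1; c <= 4; ++c) {
    std::vector<int> cruns;
    for (int i = 0; i < r; ++i)
      if (run_chars[i] == c) cruns.push_back(i);
    if (cruns.empty()) {
      for (int i = 0; i < r; ++i) th(i, c - 1) = 0;
      continue;
    }
    const int first = cruns.front(), last = cruns.back();
    for (int i = 0; i < first; ++i) th(i, c - 1) = 0;             // absent above
    for (int i = last + 1; i < r; ++i) th(i, c - 1) = run_lens[i]; // absent below
    for (size_t t = 0; t + 1 < cruns.size(); ++t) {
      const int a = cruns[t], b = cruns[t + 1];
      if (b == a + 1) continue;
      const int prev_end = run_starts[a] + run_lens[a] - 1;
      const int next_start = run_starts[b];
      int best = INT_MAX, bpos = prev_end + 1;
      for (int p = prev_end + 1; p <= next_start; ++p) {
        if (lcp[p] < best) { best = lcp[p]; bpos = p; }
      }
      for (int i = a + 1; i < b; ++i) {
        int off = bpos - run_starts[i];
        if (off < 0) off = 0;
        if (off > run_lens[i]) off = run_lens[i];
        th(i, c - 1) = off;
      }
    }
    for (size_t t = 0; t < cruns.size(); ++t) th(cruns[t], c - 1) = NA_INTEGER;
  }
  return th;
}

// For every run and every character c, the index of the nearest run with
// character c strictly above (smaller index) and strictly below (larger
// index); -1 when none exists. Used for O(1) repositioning.
// [[Rcpp::export]]
List nearest_char_runs(IntegerVector run_chars) {
  const int r = run_chars.size();
  IntegerMatrix up(r, 4), down(r, 4);
  int seen[5];
  for (int c = 0; c < 5; ++c) seen[c] = -1;
  for (int i = 0; i < r; ++i) {
    for (int c = 1; c <= 4; ++c) up(i, c - 1) = seen[c];
    if (run_chars[i] >= 1 && run_chars[i] <= 4) seen[run_chars[i]] = i;
  }
  for (int c = 0; c < 5; ++c) seen[c] = -1;
  for (int i = r - 1; i >= 0; --i) {
    for (int c = 1; c <= 4; ++c) down(i, c - 1) = seen[c];
    if (run_chars[i] >= 1 && run_chars[i] <= 4) seen[run_chars[i]] = i;
  }
  return List::create(_["up"] = up, _["down"] = down);
}

// Pseudo-matching length query over the move table.
//
// Walks the read right-to-left tracking a single (run, offset) position.
// Case 1 (character matches the run character): the current length grows by
// one. Case 2: reposition up or down according to the strategy's effective
// threshold, then reset the length to zero. After recording pml[k] the
// LF-mapping is applied (table hop + fast-forward across run boundaries) and
// the post-LF run index is recorded in visited[k] (0-based; NA for skipped
// positions). Read characters outside A,C,G,T, or absent from the BWT, give
// pml 0 and leave the position unchanged.
//
// strategy: 0 = true thresholds, 1 = mid-run (ceil(n/2)), 2 = always-up.
// [[Rcpp::export]]
List pml_query(IntegerVector run_chars, IntegerVector run_lens,
               IntegerVector dest_run, IntegerVector dest_off,
               Nullable<IntegerMatrix> thresholds,
               IntegerMatrix up_run, IntegerMatrix down_run,
               IntegerVector read, int strategy) {
  const int r = run_chars.size();
  const int m = read.size();
  IntegerVector pml(m), visited(m);
  bool present[5] = {false, false, false, false, false};
  for (int i = 0; i < r; ++i)
    if (run_chars[i] >= 0 && run_chars[i] <= 4) present[run_chars[i]] = true;
  IntegerMatrix th;
  if (strategy == 0) {
    if (thresholds.isNull()) stop("true-threshold strategy requires thresholds");
    th = thresholds.get();
  }
  int i = r - 1, j = run_lens[r - 1] - 1, ell = 0;
  for (int k = m - 1; k >= 0; --k) {
    const int c = read[k];
    if (c < 1 || c > 4 || !present[c]) {
      ell = 0;
      pml[k] = 0;
      visited[k] = NA_INTEGER;
      continue;
    }
    if (run_chars[i] == c) {
      ++ell;                                        // case 1
    } else {                                        // case 2: reposition
      const int n_run = run_lens[i];
      int thr;
      if (strategy == 0) thr = th(i, c - 1);
      else if (strategy == 1) thr = (n_run + 1) / 2;
      else thr = n_run;
      const int ui = up_run(i, c - 1), di = down_run(i, c - 1);
      if (j < thr) {
        if (ui >= 0) { i = ui; j = run_lens[ui] - 1; }
        else         { i = di; j = 0; }
      } else {
        if (di >= 0) { i = di; j = 0; }
        else         { i = ui; j = run_lens[ui] - 1; }
      }
      ell = 0;
    }
    pml[k] = ell;
    // LF step with fast-forward
    int ii = dest_run[i];
    long long jj = (long long)dest_off[i] + j;
    while (jj >= run_lens[ii]) { jj -= run_lens[ii]; ++ii; }
    i = ii;
    j = (int)jj;
    visited[k] = i;
  }
  return List::create(_["pml"] = pml, _["visited"] = visited);
}
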
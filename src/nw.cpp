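#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

// Global (end-gap penalised) Needleman-Wunsch with linear gap costs.
// Traceback ties are broken diagonal > up (gap in b) > left (gap in a),
// which makes the returned alignment deterministic.
//
// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b,
                  int match = 1, int mismatch = -1, int gap = -2) {
  const int n = (int)a.size();
  const int m = (int)b.size();
  // score matrix, row-major, (n+1) x (m+1)
  std::vector<int> S((size_t)(n + 1) * (m + 1));
  for (int j = 0; j <= m; ++j) S[j] = j * gap;
  for (int i = 1; i <= n; ++i) {
    S[(size_t)i * (m + 1)] = i * gap;
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int sub = (ai == b[j - 1]) ? match : mismatch;
      int best = S[(size_t)(i - 1) * (m + 1) + (j - 1)] + sub;
      const int up = S[(size_t)(i - 1) * (m + 1) + j] + gap;
      if (up > best) best = up;
      const int left = S[(size_t)i * (m + 1) + (j - 1)] + gap;
      if (left > best) best = left;
      S[(size_t)i * (m + 1) + j] = best;
    }
  }
  // traceback with the stated preference order
  std::string ra, rb;
  ra.reserve(n + m);
  rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int cur = S[(size_t)i * (m + 1) + j];
    if (i > 0 && j > 0) {
      const int sub = (a[i - 1] == b[j - 1]) ? match : mismatch;
      if (cur == S[(size_t)(i - 1) * (m + 1) + (j - 1)] + sub) {
        ra.push_back(a[i - 1]);
        rb.push_back(b[j - 1]);
        --i; --j;
        continue;
      }
    }
    if (i > 0 && cur == S[(size_t)(i - 1) * (m + 1) + j] + gap) {
      ra.push_back(a[i - 1]);
      rb.push_back('-');
      --i;
      continue;
    }
    // must be left
    ra.push_back('-');
    rb.push_back(b[j - 1]);
    --j;
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["score"] = S[(size_t)n * (m + 1) + m],
                      _["aligned_a"] = ra,
                      _["aligned_b"] = rb);
}

// Longest strictly increasing subsequence by patience sorting; returns the
// 1-based indices of one maximum-cardinality chain. Deterministic: at every
// chain length the smallest feasible tail value is kept.
//
// [[Rcpp::export(name = ".lis_cpp")]]
IntegerVector lis_cpp(IntegerVector x) {
  const int n = x.size();
  if (n == 0) return IntegerVector(0);
  std::vector<int> tails;      // smallest tail value per chain length
  std::vector<int> tidx;       // index achieving it
  std::vector<int> pred(n, -1);
  tails.reserve(n);
  tidx.reserve(n);
  for (int i = 0; i < n; ++i) {
    // first position with tails[j] >= x[i]  (strict increase)
    int lo = std::lower_bound(tails.begin(), tails.end(), x[i]) -
      tails.begin();
    pred[i] = (lo > 0) ? tidx[lo - 1] : -1;
    if (lo == (int)tails.size()) {
      tails.push_back(x[i]);
      tidx.push_back(i);
    } else if (x[i] < tails[lo]) {
      tails[lo] = x[i];
      tidx[lo] = i;
    }
  }
  const int len = (int)tails.size();
  IntegerVector out(len);
  int cur = tidx[len - 1];
  for (int r = len - 1; r >= 0; --r) {
    out[r] = cur + 1;
    cur = pred[cur];
  }
  return out;
}

// Hamming distance of equal-length strings (helper for the substitution
// shortcut and for strand assignment in the census).
//
// [[Rcpp::export(name = ".hamming_cpp")]]
int hamming_cpp(std::string a, std::string b) {
  if (a.size() != b.size()) stop("hamming: unequal lengths");
  int d = 0;
  for (size_t i = 0; i < a.size(); ++i)
    if (a[i] != b[i]) ++d;
  return d;
}
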
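#include <Rcpp.h>
#include <climits>
#include <vector>
#include <utility>
using namespace Rcpp;

// N never matches anything, including another N.
static inline int sub_cost(char a, char b) {
  if (a == 'N' || b == 'N') return 1;
  return a == b ? 0 : 1;
}

// Best semi-global (free text start/end) match of the full pattern inside the
// text, by Levenshtein distance. Ties: smaller start, then smaller end.
// Returns c(dist, start, end) with a 0-based half-open span, or dist = NA when
// either string is empty.
// [[Rcpp::export]]
IntegerVector adapter_scan_full(std::string text, std::string pat) {
  int n = (int)text.size(), m = (int)pat.size();
  if (n == 0 || m == 0)
    return IntegerVector::create(NA_INTEGER, NA_INTEGER, NA_INTEGER);
  std::vector<int> prev(n + 1), cur(n + 1), sprev(n + 1), scur(n + 1);
  for (int j = 0; j <= n; ++j) { prev[j] = 0; sprev[j] = j; }
  for (int i = 1; i <= m; ++i) {
    cur[0] = i; scur[0] = 0;
    for (int j = 1; j <= n; ++j) {
      int d = prev[j - 1] + sub_cost(pat[i - 1], text[j - 1]);
      int s = sprev[j - 1];
      if (prev[j] + 1 < d || (prev[j] + 1 == d && sprev[j] < s)) {
        d = prev[j] + 1; s = sprev[j];
      }
      if (cur[j - 1] + 1 < d || (cur[j - 1] + 1 == d && scur[j - 1] < s)) {
        d = cur[j - 1] + 1; s = scur[j - 1];
      }
      cur[j] = d; scur[j] = s;
    }
    std::swap(prev, cur); std::swap(sprev, scur);
  }
  int best = INT_MAX, bs = -1, be = -1;
  for (int j = 0; j <= n; ++j) {
    int d = prev[j], s = sprev[j];
    if (d < best || (d == best && (s < bs || (s == bs && j < be)))) {
      best = d; bs = s; be = j;
    }
  }
  return IntegerVector::create(best, bs, be);
}

// Best match of a pattern *suffix* (length L in [min_overlap, m-1]) anchored
// at the very start of the text; per-candidate error budget is
// floor(max_error_rate * L). Ranking: smaller distance, then larger overlap,
// then smaller end. Returns c(dist, overlap, end) or NAs when nothing passes.
// [[Rcpp::export]]
IntegerVector adapter_scan_start(std::string text, std::string pat,
                                 int min_overlap, double max_error_rate) {
  int n = (int)text.size(), m = (int)pat.size();
  int bestd = INT_MAX, bestL = -1, bestend = INT_MAX;
  for (int L = min_overlap; L <= m - 1; ++L) {
    int allowed = (int)std::floor(max_error_rate * L);
    const char* p = pat.c_str() + (m - L);
    int jmax = std::min(n, L + allowed);
    std::vector<int> prev(jmax + 1), cur(jmax + 1);
    for (int j = 0; j <= jmax; ++j) prev[j] = j;
    for (int i = 1; i <= L; ++i) {
      cur[0] = i;
      for (int j = 1; j <= jmax; ++j) {
        int d = prev[j - 1] + sub_cost(p[i - 1], text[j - 1]);
        if (prev[j] + 1 < d) d = prev[j] + 1;
        if (cur[j - 1] + 1 < d) d = cur[j - 1] + 1;
        cur[j] = d;
      }
      std::swap(prev, cur);
    }
    for (int j = 0; j <= jmax; ++j) {
      int d = prev[j];
      if (d > allowed) continue;
      if (d < bestd || (d == bestd && (L > bestL || (L == bestL && j < bestend)))) {
        bestd = d; bestL = L; bestend = j;
      }
    }
  }
  if (bestd == INT_MAX)
    return IntegerVector::create(NA_INTEGER, NA_INTEGER, NA_INTEGER);
  return IntegerVector::create(bestd, bestL, bestend);
}

// 3'-most homopolymer run of `target` with at most max_mismatch other bases,
// length >= min_run, first and last base equal to target. Returns a 0-based
// half-open span or NAs.
// [[Rcpp::export]]
IntegerVector polya_scan(std::string s, char target, int min_run,
                         int max_mismatch) {
  int n = (int)s.size();
  for (int j = n - 1; j >= min_run - 1; --j) {
    if (s[j] != target) continue;
    int mism = 0, bestStart = -1;
    for (int i = j; i >= 0; --i) {
      if (s[i] != target) {
        if (++mism > max_mismatch) break;
      } else if (j - i + 1 >= min_run) {
        bestStart = i;
      }
    }
    if (bestStart >= 0)
      return IntegerVector::create(bestStart, j + 1);
  }
  return IntegerVector::create(NA_INTEGER, NA_INTEGER);
}

// Fast reverse complement for plain ACGTN strings.
// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector x) {
  int n = x.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(x[i]);
    std::string r(s.rbegin(), s.rend());
    for (size_t j = 0; j < r.size(); ++j) {
      switch (r[j]) {
      case 'A': r[j] = 'T'; break;
      case 'C': r[j] = 'G'; break;
      case 'G': r[j] = 'C'; break;
      case 'T': r[j] = 'A'; break;
      default: break;
      }
    }
    out[i] = r;
  }
  return out;
}

// 8-connected component labelling of a logical mask; labels are assigned in
// column-major scan order starting at 1.
// [[Rcpp::export]]
IntegerMatrix label_components(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0)) continue;
      ++next;
      lab(r0, c0) = next;
      stack.push_back(std::make_pair(r0, c0));
      while (!stack.empty()) {
        std::pair<int, int> rc = stack.back();
        stack.pop_back();
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            int r = rc.first + dr, c = rc.second + dc;
            if (r < 0 || c < 0 || r >= nr || c >= nc) continue;
            if (mask(r, c) && !lab(r, c)) {
              lab(r, c) = next;
              stack.push_back(std::make_pair(r, c));
            }
          }
        }
      }
    }
  }
  return lab;
}
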
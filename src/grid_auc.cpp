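// Fast Mann-Whitney AUC and exhaustive weight-grid search used by
// grid_train(). Orientation throughout: smaller score = more positive.

#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// tie-aware AUC for smaller-is-positive scores, given a workspace of
// indices; equals U / (n_pos * n_neg) with ties counted one half
static double auc_from_scores(const std::vector<double>& s,
                              const std::vector<int>& pos_flag,
                              std::vector<int>& idx) {
  const int n = (int) s.size();
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&s](int a, int b) { return s[a] < s[b]; });
  long double rank_sum_pos = 0.0;  // tie-averaged ascending ranks
  int m = 0;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && s[idx[j + 1]] == s[idx[i]]) ++j;
    double avg_rank = (i + j) / 2.0 + 1.0;  // 1-based
    for (int k = i; k <= j; ++k) {
      if (pos_flag[idx[k]]) { rank_sum_pos += avg_rank; ++m; }
    }
    i = j + 1;
  }
  const int nn = n - m;
  // smaller-is-positive: descending ranks are (n + 1 - ascending)
  long double rank_sum_desc = (long double)m * (n + 1) - rank_sum_pos;
  return (double)((rank_sum_desc - (long double)m * (m + 1) / 2.0) /
                  ((long double)m * nn));
}

// [[Rcpp::export(name = ".cpp_auc_smaller_positive")]]
double cpp_auc_smaller_positive(NumericVector scores, LogicalVector pos) {
  const int n = scores.size();
  std::vector<double> s(scores.begin(), scores.end());
  std::vector<int> pf(n);
  for (int i = 0; i < n; ++i) pf[i] = pos[i] == TRUE;
  std::vector<int> idx(n);
  return auc_from_scores(s, pf, idx);
}

// Exhaustive grid search of the training AUC of the score
// logt + wh * H + wo * (1 - D); returns c(wh, wo, auc) with ties broken
// to the lexicographically smallest (wh, wo) (grids must be ascending).
// [[Rcpp::export(name = ".cpp_grid_argmax")]]
NumericVector cpp_grid_argmax(NumericVector logt, NumericVector H,
                              NumericVector od, LogicalVector pos,
                              NumericVector grid_wh, NumericVector grid_wo) {
  const int n = logt.size();
  std::vector<int> pf(n);
  for (int i = 0; i < n; ++i) pf[i] = pos[i] == TRUE;
  std::vector<double> base(n), s(n);
  std::vector<int> idx(n);
  double best_auc = -1.0, best_wh = NA_REAL, best_wo = NA_REAL;
  for (int a = 0; a < grid_wh.size(); ++a) {
    const double wh = grid_wh[a];
    for (int i = 0; i < n; ++i) base[i] = logt[i] + wh * H[i];
    for (int b = 0; b < grid_wo.size(); ++b) {
      const double wo = grid_wo[b];
      for (int i = 0; i < n; ++i) s[i] = base[i] + wo * od[i];
      const double auc = auc_from_scores(s, pf, idx);
      if (auc > best_auc) { best_auc = auc; best_wh = wh; best_wo = wo; }
    }
  }
  return NumericVector::create(best_wh, best_wo, best_auc);
}
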
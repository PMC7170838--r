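// Exhaustive best-subset search under AICc via the sweep operator.
// Subsets are visited in Gray-code order so each step sweeps exactly one
// pivot of the centered cross-product matrix; the residual sum of squares of
// the current subset is then the (y, y) element. The sweep uses the
// reversible (Goodnight) sign convention, so re-sweeping a pivot undoes it.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline void sweep_pivot(std::vector<double>& A, const int dim,
                               const int k) {
  const double d = A[k + dim * k];
  for (int j = 0; j < dim; ++j) {
    if (j == k) continue;
    const double Akj = A[k + dim * j];
    if (Akj != 0.0) {
      for (int i = 0; i < dim; ++i) {
        if (i == k) continue;
        A[i + dim * j] -= A[i + dim * k] * Akj / d;
      }
    }
    A[k + dim * j] = -Akj / d;
  }
  for (int i = 0; i < dim; ++i) {
    if (i != k) A[i + dim * k] /= d;
  }
  A[k + dim * k] = 1.0 / d;
}

// [[Rcpp::export]]
List gray_sweep_search(NumericMatrix M, int n, int topk,
                       bool return_all = false) {
  const int dim = M.ncol();
  const int m = dim - 1;          // number of candidate predictors
  const int yi = m;               // index of the response block
  if (m < 0 || m > 30) stop("candidate count out of range");
  std::vector<double> A(M.begin(), M.end());

  const uint64_t total = 1ULL << m;
  std::vector<double> top_aicc(topk, R_PosInf);
  std::vector<double> top_rss(topk, NA_REAL);
  std::vector<double> top_mask(topk, NA_REAL);
  double best_aicc = R_PosInf, best_rss = NA_REAL;
  uint64_t best_mask = 0;
  double evaluated = 0, skipped = 0;
  NumericVector all_aicc(return_all ? total : 0, NA_REAL);

  auto eval_current = [&](uint64_t mask, int ksize) {
    const double p = ksize + 2.0;        // slopes + intercept + error variance
    if (n - p - 1.0 < 1.0) { skipped += 1; return; }
    const double rss = A[yi + dim * yi];
    if (!(rss > 0.0) || !std::isfinite(rss)) { skipped += 1; return; }
    const double aicc = n * std::log(2.0 * M_PI * rss / n) + n + 2.0 * p +
                        2.0 * p * (p + 1.0) / (n - p - 1.0);
    evaluated += 1;
    if (return_all) all_aicc[mask] = aicc;
    if (aicc < best_aicc) {
      best_aicc = aicc; best_rss = rss; best_mask = mask;
    }
    if (aicc < top_aicc[topk - 1]) {
      int pos = topk - 1;
      while (pos > 0 && top_aicc[pos - 1] > aicc) {
        top_aicc[pos] = top_aicc[pos - 1];
        top_rss[pos] = top_rss[pos - 1];
        top_mask[pos] = top_mask[pos - 1];
        --pos;
      }
      top_aicc[pos] = aicc;
      top_rss[pos] = rss;
      top_mask[pos] = static_cast<double>(mask);
    }
  };

  eval_current(0, 0);  // intercept-only model
  uint64_t gray_prev = 0;
  for (uint64_t i = 1; i < total; ++i) {
    const uint64_t gray = i ^ (i >> 1);
    const int bit = __builtin_ctzll(gray ^ gray_prev);
    sweep_pivot(A, dim, bit);
    gray_prev = gray;
    eval_current(gray, __builtin_popcountll(gray));
    if ((i & 0xFFFFFULL) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["best_mask"] = static_cast<double>(best_mask),
    _["best_rss"] = best_rss,
    _["best_aicc"] = best_aicc,
    _["n_evaluated"] = evaluated,
    _["n_skipped"] = skipped,
    _["top_mask"] = NumericVector(top_mask.begin(), top_mask.end()),
    _["top_rss"] = NumericVector(top_rss.begin(), top_rss.end()),
    _["top_aicc"] = NumericVector(top_aicc.begin(), top_aicc.end()),
    _["all_aicc"] = all_aicc);
}
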
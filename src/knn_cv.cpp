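// Cross-validated k-nearest-neighbour voting with per-fold standardisation.
//
// Predictors are centred and scaled using statistics of the training folds
// only; the held-out fold is scaled with those same statistics (no leakage).
// Distances are Euclidean; neighbour order is deterministic (ties on
// distance break toward the smaller training-row index).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// votes[t, j] = fraction of the ks[j] nearest training neighbours of
// held-out point t that carry label 1. Points in fold 0 are never held out.
static void cv_votes_core(const std::vector<double>& X, int n, int p,
                          const int* y, const int* fold,
                          const std::vector<int>& ks,
                          std::vector<double>& votes) {
  int nk = (int)ks.size();
  int kmax = 0, nf = 0;
  for (int j = 0; j < nk; ++j) kmax = std::max(kmax, ks[j]);
  for (int i = 0; i < n; ++i) nf = std::max(nf, fold[i]);
  std::vector<int> tr, te;
  std::vector<double> mu(p), sdv(p);
  std::vector<double> A, q;               // scaled train (row-major), query
  std::vector<std::pair<double, int> > dist;
  for (int f = 1; f <= nf; ++f) {
    tr.clear(); te.clear();
    for (int i = 0; i < n; ++i) (fold[i] == f ? te : tr).push_back(i);
    int ntr = (int)tr.size();
    if (te.empty() || ntr == 0) continue;
    for (int j = 0; j < p; ++j) {
      double s = 0.0;
      for (size_t a = 0; a < tr.size(); ++a) s += X[(size_t)j * n + tr[a]];
      double m = s / ntr, ss = 0.0;
      for (size_t a = 0; a < tr.size(); ++a) {
        double d = X[(size_t)j * n + tr[a]] - m; ss += d * d;
      }
      mu[j] = m;
      sdv[j] = ntr > 1 ? std::sqrt(ss / (ntr - 1)) : 0.0;
      if (sdv[j] <= 0.0) sdv[j] = 1.0;   // constant predictor: centre only
    }
    // scaled training points, one point per contiguous row
    A.assign((size_t)ntr * p, 0.0);
    for (int j = 0; j < p; ++j) {
      double m = mu[j], s = sdv[j];
      for (int a = 0; a < ntr; ++a)
        A[(size_t)a * p + j] = (X[(size_t)j * n + tr[a]] - m) / s;
    }
    q.resize(p);
    for (size_t b = 0; b < te.size(); ++b) {
      int t = te[b];
      for (int j = 0; j < p; ++j)
        q[j] = (X[(size_t)j * n + t] - mu[j]) / sdv[j];
      dist.clear();
      dist.reserve(ntr);
      const double* qp = q.data();
      for (int a = 0; a < ntr; ++a) {
        const double* xp = &A[(size_t)a * p];
        double d2 = 0.0;
        for (int j = 0; j < p; ++j) {
          double d = qp[j] - xp[j];
          d2 += d * d;
        }
        dist.push_back(std::make_pair(d2, tr[a]));
      }
      int kk = std::min(kmax, ntr);
      std::partial_sort(dist.begin(), dist.begin() + kk, dist.end());
      for (int j = 0; j < nk; ++j) {
        int k = std::min(ks[j], ntr);
        int pos = 0;
        for (int s = 0; s < k; ++s) pos += y[dist[s].second];
        votes[(size_t)j * n + t] = (double)pos / k;
      }
    }
  }
}

static std::vector<double> flatten(const NumericMatrix& X) {
  std::vector<double> v(X.begin(), X.end());
  return v;
}

// [[Rcpp::export]]
NumericMatrix knn_cv_votes_cpp(NumericMatrix X, IntegerVector y,
                               IntegerVector fold, IntegerVector ks) {
  int n = X.nrow(), p = X.ncol();
  std::vector<int> kv(ks.begin(), ks.end());
  std::vector<double> xv = flatten(X);
  std::vector<double> votes((size_t)n * kv.size(), NA_REAL);
  cv_votes_core(xv, n, p, INTEGER(y), INTEGER(fold), kv, votes);
  NumericMatrix out(n, (int)kv.size());
  std::copy(votes.begin(), votes.end(), out.begin());
  return out;
}

// Same as above for a single k, with one row of X replaced (1-based
// swap_row; 0 = none). Used for perturbed-feature re-evaluation without
// copying the matrix in R.
// [[Rcpp::export]]
NumericVector knn_cv_votes_swap_cpp(NumericMatrix X, IntegerVector y,
                                    IntegerVector fold, int k,
                                    int swap_row, NumericVector new_row) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> xv = flatten(X);
  if (swap_row > 0) {
    for (int j = 0; j < p; ++j) xv[(size_t)j * n + (swap_row - 1)] = new_row[j];
  }
  std::vector<int> kv(1, k);
  std::vector<double> votes((size_t)n, NA_REAL);
  cv_votes_core(xv, n, p, INTEGER(y), INTEGER(fold), kv, votes);
  return NumericVector(votes.begin(), votes.end());
}
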
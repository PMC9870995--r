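// Compact CART random forest (regression + binary classification-as-probability).
//
// Trees are grown on bootstrap samples with per-node feature subsampling (mtry),
// split by variance reduction (equivalent to Gini for 0/1 labels), leaves predict
// the node mean.  Forest output is the mean over trees, i.e. a probability for
// 0/1 labels.  Variable importance is out-of-bag permutation importance (mean
// increase in OOB MSE / misclassification rate after permuting one feature).
// All randomness flows from one std::mt19937_64 seed so results are exactly
// reproducible across platforms.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct Node {
  int feature;      // -1 for leaf
  double threshold; // split: x <= threshold goes left
  int left, right;
  double value;     // leaf prediction (node mean of y)
};

struct Tree {
  std::vector<Node> nodes;

  double predict_row(const double *x) const {
    int k = 0;
    while (nodes[k].feature >= 0) {
      k = (x[nodes[k].feature] <= nodes[k].threshold) ? nodes[k].left
                                                      : nodes[k].right;
    }
    return nodes[k].value;
  }
};

class Builder {
public:
  Builder(const NumericMatrix &X, const NumericVector &y, int mtry,
          int min_node, std::mt19937_64 &rng)
      : X_(X), y_(y), n_(X.nrow()), p_(X.ncol()), mtry_(mtry),
        min_node_(min_node), rng_(rng) {
    feat_pool_.resize(p_);
    for (int j = 0; j < p_; ++j) feat_pool_[j] = j;
  }

  Tree grow(const std::vector<int> &sample_idx) {
    idx_ = sample_idx;
    tree_.nodes.clear();
    build(0, static_cast<int>(idx_.size()));
    return tree_;
  }

private:
  const NumericMatrix &X_;
  const NumericVector &y_;
  int n_, p_, mtry_, min_node_;
  std::mt19937_64 &rng_;
  std::vector<int> idx_;
  std::vector<int> feat_pool_;
  std::vector<std::pair<double, double>> buf_; // (x value, y)
  Tree tree_;

  // build node over idx_[lo, hi); returns node index
  int build(int lo, int hi) {
    const int m = hi - lo;
    double sum = 0.0, sum2 = 0.0;
    for (int k = lo; k < hi; ++k) {
      const double v = y_[idx_[k]];
      sum += v;
      sum2 += v * v;
    }
    const double mean = sum / m;
    const int me = static_cast<int>(tree_.nodes.size());
    tree_.nodes.push_back({-1, 0.0, -1, -1, mean});

    const bool pure = (sum2 - sum * sum / m) <= 1e-12 * (std::abs(sum2) + 1.0);
    if (m <= min_node_ || pure) return me;

    // sample mtry features without replacement (partial Fisher-Yates)
    for (int j = 0; j < mtry_; ++j) {
      std::uniform_int_distribution<int> pick(j, p_ - 1);
      std::swap(feat_pool_[j], feat_pool_[pick(rng_)]);
    }

    int best_feat = -1;
    double best_gain = sum * sum / m; // gain of not splitting
    double best_thr = 0.0;
    for (int j = 0; j < mtry_; ++j) {
      const int f = feat_pool_[j];
      buf_.resize(m);
      for (int k = 0; k < m; ++k)
        buf_[k] = {X_(idx_[lo + k], f), y_[idx_[lo + k]]};
      std::sort(buf_.begin(), buf_.end());
      double sl = 0.0;
      for (int k = 0; k < m - 1; ++k) {
        sl += buf_[k].second;
        if (buf_[k].first == buf_[k + 1].first) continue;
        const double sr = sum - sl;
        const double gain =
            sl * sl / (k + 1) + sr * sr / (m - k - 1);
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_feat = f;
          best_thr = 0.5 * (buf_[k].first + buf_[k + 1].first);
        }
      }
    }
    if (best_feat < 0) return me;

    // partition idx_[lo,hi) in place
    int i = lo, j = hi - 1;
    while (i <= j) {
      if (X_(idx_[i], best_feat) <= best_thr) {
        ++i;
      } else {
        std::swap(idx_[i], idx_[j]);
        --j;
      }
    }
    if (i == lo || i == hi) return me; // numeric safety; keep leaf

    tree_.nodes[me].feature = best_feat;
    tree_.nodes[me].threshold = best_thr;
    const int l = build(lo, i);
    tree_.nodes[me].left = l;
    const int r = build(i, hi);
    tree_.nodes[me].right = r;
    return me;
  }
};

inline double row_predict(const Tree &t, const NumericMatrix &X, int i,
                          std::vector<double> &rowbuf) {
  const int p = X.ncol();
  for (int j = 0; j < p; ++j) rowbuf[j] = X(i, j);
  return t.predict_row(rowbuf.data());
}

// error contribution of a single prediction
inline double err1(double pred, double truth, bool classify) {
  if (classify) return ((pred >= 0.5 ? 1.0 : 0.0) != truth) ? 1.0 : 0.0;
  const double d = pred - truth;
  return d * d;
}

} // namespace

// Fit a forest; return test-set predictions, OOB predictions and (optionally)
// OOB permutation importance.  y must be numeric; for classification pass 0/1
// and classify = TRUE (affects only the error measure used for VIMP).
// [[Rcpp::export]]
List cpp_rf(NumericMatrix X, NumericVector y, NumericMatrix Xtest, int ntree,
            int mtry, int min_node, bool classify, bool vimp, double seed) {
  const int n = X.nrow(), p = X.ncol(), nt = Xtest.nrow();
  std::mt19937_64 rng(static_cast<std::uint64_t>(seed));
  std::uniform_int_distribution<int> unif_n(0, n - 1);

  Builder builder(X, y, mtry, min_node, rng);
  NumericVector pred_test(nt, 0.0), pred_oob(n, 0.0), imp(p, 0.0);
  std::vector<int> oob_count(n, 0);
  std::vector<double> imp_acc(p, 0.0);
  std::vector<int> imp_trees(p, 0);
  std::vector<double> rowbuf(p);
  std::vector<int> sample_idx(n);
  std::vector<char> inbag(n);
  std::vector<int> oob;
  std::vector<double> xsave;

  for (int t = 0; t < ntree; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    for (int k = 0; k < n; ++k) {
      sample_idx[k] = unif_n(rng);
      inbag[sample_idx[k]] = 1;
    }
    Tree tree = builder.grow(sample_idx);

    for (int i = 0; i < nt; ++i)
      pred_test[i] += row_predict(tree, Xtest, i, rowbuf);

    oob.clear();
    for (int i = 0; i < n; ++i)
      if (!inbag[i]) oob.push_back(i);
    std::vector<double> oob_pred(oob.size());
    double base_err = 0.0;
    for (size_t k = 0; k < oob.size(); ++k) {
      oob_pred[k] = row_predict(tree, X, oob[k], rowbuf);
      pred_oob[oob[k]] += oob_pred[k];
      ++oob_count[oob[k]];
      base_err += err1(oob_pred[k], y[oob[k]], classify);
    }
    if (vimp && !oob.empty()) {
      const int no = static_cast<int>(oob.size());
      base_err /= no;
      xsave.resize(no);
      std::vector<int> perm(no);
      for (int j = 0; j < p; ++j) {
        for (int k = 0; k < no; ++k) perm[k] = k;
        for (int k = no - 1; k > 0; --k) {
          std::uniform_int_distribution<int> pick(0, k);
          std::swap(perm[k], perm[pick(rng)]);
        }
        double perr = 0.0;
        for (int k = 0; k < no; ++k) {
          const int i = oob[k];
          for (int c = 0; c < p; ++c) rowbuf[c] = X(i, c);
          rowbuf[j] = X(oob[perm[k]], j);
          perr += err1(tree.predict_row(rowbuf.data()), y[i], classify);
        }
        imp_acc[j] += perr / no - base_err;
        ++imp_trees[j];
      }
    }
  }

  for (int i = 0; i < nt; ++i) pred_test[i] /= ntree;
  for (int i = 0; i < n; ++i)
    pred_oob[i] = oob_count[i] > 0 ? pred_oob[i] / oob_count[i] : NA_REAL;
  if (vimp)
    for (int j = 0; j < p; ++j)
      imp[j] = imp_trees[j] > 0 ? imp_acc[j] / imp_trees[j] : 0.0;

  return List::create(_["pred_test"] = pred_test, _["pred_oob"] = pred_oob,
                      _["vimp"] = imp);
}

// K-fold cross-validated predictions: fold is a 1-based fold id per row.
// One forest per fold, trained on the complement, predicting the fold.
// [[Rcpp::export]]
NumericVector cpp_rf_cv(NumericMatrix X, NumericVector y, IntegerVector fold,
                        int ntree, int mtry, int min_node, double seed) {
  const int n = X.nrow(), p = X.ncol();
  int nfold = 0;
  for (int i = 0; i < n; ++i) nfold = std::max(nfold, fold[i]);
  NumericVector out(n, NA_REAL);
  std::mt19937_64 rng(static_cast<std::uint64_t>(seed));

  std::vector<int> tr, te;
  for (int f = 1; f <= nfold; ++f) {
    tr.clear();
    te.clear();
    for (int i = 0; i < n; ++i) (fold[i] == f ? te : tr).push_back(i);
    if (te.empty()) continue;
    const int m = static_cast<int>(tr.size());
    NumericMatrix Xtr(m, p), Xte(static_cast<int>(te.size()), p);
    NumericVector ytr(m);
    for (int k = 0; k < m; ++k) {
      ytr[k] = y[tr[k]];
      for (int j = 0; j < p; ++j) Xtr(k, j) = X(tr[k], j);
    }
    for (size_t k = 0; k < te.size(); ++k)
      for (int j = 0; j < p; ++j) Xte(static_cast<int>(k), j) = X(te[k], j);

    Builder builder(Xtr, ytr, mtry, min_node, rng);
    std::uniform_int_distribution<int> unif_m(0, m - 1);
    std::vector<int> sample_idx(m);
    std::vector<double> rowbuf(p);
    std::vector<double> acc(te.size(), 0.0);
    for (int t = 0; t < ntree; ++t) {
      for (int k = 0; k < m; ++k) sample_idx[k] = unif_m(rng);
      Tree tree = builder.grow(sample_idx);
      for (size_t k = 0; k < te.size(); ++k)
        acc[k] += row_predict(tree, Xte, static_cast<int>(k), rowbuf);
    }
    for (size_t k = 0; k < te.size(); ++k) out[te[k]] = acc[k] / ntree;
  }
  return out;
}
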
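#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Compact CART kernels used by the classifier bank: a weighted Gini
// classification tree (decision tree, random forest, AdaBoost) and a
// second-order gradient tree (XGBoost-style booster). Trees are stored as
// flat parallel arrays; feature == -1 marks a leaf.

struct NodeTask {
  std::vector<int> idx;
  int depth;
  int node;
};

// Grow one classification tree. X: n x p, y in 0..K-1, w sample weights.
// mtry features are drawn per node through R's RNG (reproducible via
// set.seed on the R side).
// [[Rcpp::export(name = ".grow_class_tree")]]
List grow_class_tree(NumericMatrix X, IntegerVector y, NumericVector w,
                     int K, int max_depth, int min_split, int mtry,
                     Nullable<IntegerVector> rows_ = R_NilValue) {
  int n_all = X.nrow(), p = X.ncol();
  std::vector<int> feature, left, right;
  std::vector<double> threshold;
  std::vector< std::vector<double> > probs;

  std::vector<NodeTask> stack;
  NodeTask root;
  if (rows_.isNotNull()) {
    IntegerVector rows(rows_);           // 1-based bootstrap rows
    root.idx.reserve(rows.size());
    for (int i = 0; i < rows.size(); ++i) root.idx.push_back(rows[i] - 1);
  } else {
    root.idx.reserve(n_all);
    for (int i = 0; i < n_all; ++i) root.idx.push_back(i);
  }
  if (root.idx.empty()) stop("empty training set");
  root.depth = 0;
  root.node = 0;
  feature.push_back(-1); threshold.push_back(0.0);
  left.push_back(-1); right.push_back(-1);
  probs.push_back(std::vector<double>(K, 0.0));
  stack.push_back(root);

  std::vector<double> cls(K), clsL(K), clsR(K);

  while (!stack.empty()) {
    NodeTask t = stack.back();
    stack.pop_back();
    const std::vector<int>& idx = t.idx;
    int n = (int)idx.size();

    std::fill(cls.begin(), cls.end(), 0.0);
    double W = 0.0;
    for (int i = 0; i < n; ++i) { cls[y[idx[i]]] += w[idx[i]]; W += w[idx[i]]; }
    std::vector<double>& pr = probs[t.node];
    for (int k = 0; k < K; ++k) pr[k] = (W > 0) ? cls[k] / W : 1.0 / K;

    double g_parent = 1.0;
    for (int k = 0; k < K; ++k) g_parent -= pr[k] * pr[k];
    bool pure = g_parent < 1e-12;
    if (t.depth >= max_depth || n < min_split || pure || W <= 0) continue;

    // candidate features
    IntegerVector feats;
    if (mtry >= p) {
      feats = seq(1, p);
    } else {
      feats = sample(p, mtry, false);
    }

    double best_gain = 1e-10;
    int best_f = -1;
    double best_thr = 0.0;

    std::vector< std::pair<double,int> > vals(n);
    for (int fi = 0; fi < feats.size(); ++fi) {
      int f = feats[fi] - 1;
      for (int i = 0; i < n; ++i) vals[i] = std::make_pair(X(idx[i], f), idx[i]);
      std::sort(vals.begin(), vals.end());
      if (vals[0].first == vals[n - 1].first) continue;
      std::fill(clsL.begin(), clsL.end(), 0.0);
      for (int k = 0; k < K; ++k) clsR[k] = cls[k];
      double WL = 0.0, WR = W;
      for (int i = 0; i < n - 1; ++i) {
        int yi = y[vals[i].second];
        double wi = w[vals[i].second];
        clsL[yi] += wi; clsR[yi] -= wi;
        WL += wi; WR -= wi;
        if (vals[i].first == vals[i + 1].first) continue;
        if (WL <= 0 || WR <= 0) continue;
        double gl = 1.0, gr = 1.0;
        for (int k = 0; k < K; ++k) {
          double a = clsL[k] / WL, b = clsR[k] / WR;
          gl -= a * a; gr -= b * b;
        }
        double gain = g_parent - (WL * gl + WR * gr) / W;
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_f < 0) continue;

    NodeTask tl, tr;
    tl.depth = tr.depth = t.depth + 1;
    for (int i = 0; i < n; ++i) {
      if (X(idx[i], best_f) <= best_thr) tl.idx.push_back(idx[i]);
      else tr.idx.push_back(idx[i]);
    }
    if (tl.idx.empty() || tr.idx.empty()) continue;

    feature[t.node] = best_f;
    threshold[t.node] = best_thr;
    int li = (int)feature.size(), ri = li + 1;
    left[t.node] = li; right[t.node] = ri;
    for (int j = 0; j < 2; ++j) {
      feature.push_back(-1); threshold.push_back(0.0);
      left.push_back(-1); right.push_back(-1);
      probs.push_back(std::vector<double>(K, 0.0));
    }
    tl.node = li; tr.node = ri;
    stack.push_back(tl);
    stack.push_back(tr);
  }

  int nn = (int)feature.size();
  NumericMatrix pm(nn, K);
  for (int i = 0; i < nn; ++i)
    for (int k = 0; k < K; ++k) pm(i, k) = probs[i][k];
  return List::create(_["feature"] = wrap(feature),
                      _["threshold"] = wrap(threshold),
                      _["left"] = wrap(left),
                      _["right"] = wrap(right),
                      _["prob"] = pm);
}

// [[Rcpp::export(name = ".predict_class_tree")]]
NumericMatrix predict_class_tree(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"];
  NumericMatrix prob = tree["prob"];
  int n = X.nrow(), K = prob.ncol();
  NumericMatrix out(n, K);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(i, feature[node]) <= threshold[node]) ? left[node] : right[node];
    }
    for (int k = 0; k < K; ++k) out(i, k) = prob(node, k);
  }
  return out;
}

// Second-order gradient tree: g/h are per-row gradient and hessian of the
// loss; leaf weight = -G/(H + lambda); split gain follows the regularised
// objective. colsample applied per node via R's RNG when mtry < p.
// [[Rcpp::export(name = ".grow_grad_tree")]]
List grow_grad_tree(NumericMatrix X, NumericVector g, NumericVector h,
                    int max_depth, double min_child_weight, double lambda,
                    int mtry) {
  int n_all = X.nrow(), p = X.ncol();
  std::vector<int> feature, left, right;
  std::vector<double> threshold, value;

  std::vector<NodeTask> stack;
  NodeTask root;
  root.idx.reserve(n_all);
  for (int i = 0; i < n_all; ++i) root.idx.push_back(i);
  root.depth = 0; root.node = 0;
  feature.push_back(-1); threshold.push_back(0.0);
  left.push_back(-1); right.push_back(-1); value.push_back(0.0);
  stack.push_back(root);

  while (!stack.empty()) {
    NodeTask t = stack.back();
    stack.pop_back();
    const std::vector<int>& idx = t.idx;
    int n = (int)idx.size();
    double G = 0.0, H = 0.0;
    for (int i = 0; i < n; ++i) { G += g[idx[i]]; H += h[idx[i]]; }
    value[t.node] = -G / (H + lambda);
    if (t.depth >= max_depth || n < 2) continue;

    IntegerVector feats;
    if (mtry >= p) feats = seq(1, p); else feats = sample(p, mtry, false);

    double parent_score = G * G / (H + lambda);
    double best_gain = 1e-8;
    int best_f = -1;
    double best_thr = 0.0;
    std::vector< std::pair<double,int> > vals(n);
    for (int fi = 0; fi < feats.size(); ++fi) {
      int f = feats[fi] - 1;
      for (int i = 0; i < n; ++i) vals[i] = std::make_pair(X(idx[i], f), idx[i]);
      std::sort(vals.begin(), vals.end());
      if (vals[0].first == vals[n - 1].first) continue;
      double GL = 0.0, HL = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        GL += g[vals[i].second]; HL += h[vals[i].second];
        if (vals[i].first == vals[i + 1].first) continue;
        double GR = G - GL, HR = H - HL;
        if (HL < min_child_weight || HR < min_child_weight) continue;
        double gain = 0.5 * (GL * GL / (HL + lambda) + GR * GR / (HR + lambda)
                             - parent_score);
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_f < 0) continue;

    NodeTask tl, tr;
    tl.depth = tr.depth = t.depth + 1;
    for (int i = 0; i < n; ++i) {
      if (X(idx[i], best_f) <= best_thr) tl.idx.push_back(idx[i]);
      else tr.idx.push_back(idx[i]);
    }
    if (tl.idx.empty() || tr.idx.empty()) continue;
    feature[t.node] = best_f;
    threshold[t.node] = best_thr;
    int li = (int)feature.size(), ri = li + 1;
    left[t.node] = li; right[t.node] = ri;
    for (int j = 0; j < 2; ++j) {
      feature.push_back(-1); threshold.push_back(0.0);
      left.push_back(-1); right.push_back(-1); value.push_back(0.0);
    }
    tl.node = li; tr.node = ri;
    stack.push_back(tl);
    stack.push_back(tr);
  }

  return List::create(_["feature"] = wrap(feature),
                      _["threshold"] = wrap(threshold),
                      _["left"] = wrap(left),
                      _["right"] = wrap(right),
                      _["value"] = wrap(value));
}

// [[Rcpp::export(name = ".predict_grad_tree")]]
NumericVector predict_grad_tree(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"], value = tree["value"];
  int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0)
      node = (X(i, feature[node]) <= threshold[node]) ? left[node] : right[node];
    out[i] = value[node];
  }
  return out;
}
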
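#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Histogram-based regression-tree engine used by every ensemble in the
// package (the split-finding strategy of modern gradient-boosting
// libraries). Features are pre-binned once per fit into at most max_bins
// quantile bins; nodes then accumulate per-bin gradient/hessian histograms,
// so split search is O(n_node * mtry) instead of sort-based.
//
// Trees are grown on per-sample gradient (g) and hessian (h) statistics
// with an L2 penalty (lambda) on leaf values:
//   leaf value = sum(g) / (sum(h) + lambda)
//   split gain = GL^2/(HL+l) + GR^2/(HR+l) - G^2/(H+l)
// With g = y, h = 1, lambda = 0 this is an ordinary least-squares tree
// (leaf = mean, gain = SSE reduction), which backs the random forest; with
// g = y - p, h = p(1-p) it is a Newton boosting step on logistic loss.
//
// Feature subsampling (mtry) draws from R's RNG so set.seed() governs fits.

// [[Rcpp::export(name = ".make_bins")]]
List make_bins(NumericMatrix X, int max_bins = 256) {
  const int n = X.nrow(), p = X.ncol();
  IntegerMatrix B(n, p);
  List cuts(p);
  std::vector<double> col(n);
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) col[i] = X(i, j);
    std::vector<double> u(col);
    std::sort(u.begin(), u.end());
    u.erase(std::unique(u.begin(), u.end()), u.end());
    std::vector<double> cut;
    const int m = (int)u.size();
    if (m <= 1) {
      // constant feature: single bin, no cuts
    } else if (m <= max_bins) {
      cut.resize(m - 1);
      for (int k = 0; k + 1 < m; ++k) cut[k] = 0.5 * (u[k] + u[k + 1]);
    } else {
      cut.reserve(max_bins - 1);
      for (int k = 1; k < max_bins; ++k) {
        int idx = (int)((double)k * m / max_bins);
        if (idx >= m - 1) idx = m - 2;
        double c = 0.5 * (u[idx] + u[idx + 1]);
        if (cut.empty() || c > cut.back()) cut.push_back(c);
      }
    }
    for (int i = 0; i < n; ++i) {
      // bin = number of cuts strictly below x (x <= cut[b] -> bin <= b)
      B(i, j) = (int)(std::lower_bound(cut.begin(), cut.end(), col[i]) -
                      cut.begin());
    }
    cuts[j] = wrap(cut);
  }
  return List::create(_["binned"] = B, _["cuts"] = cuts);
}

struct TreeBuf {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // go left when x <= threshold
  std::vector<int> left, right;
  std::vector<double> value;
};

struct GrowCtx {
  const IntegerMatrix &B;
  const std::vector<std::vector<double> > &cuts;
  const std::vector<double> &g, &h;
  int max_depth, min_leaf, mtry;
  double lambda, min_child_weight;
  int nbins;
  std::vector<double> Gh, Hh;
  std::vector<int> Ch;
  std::vector<int> feats;
  GrowCtx(const IntegerMatrix &B_,
          const std::vector<std::vector<double> > &cuts_,
          const std::vector<double> &g_, const std::vector<double> &h_)
      : B(B_), cuts(cuts_), g(g_), h(h_) {}
};

static int grow_node(GrowCtx &ctx, std::vector<int> &rows, int lo, int hi,
                     int depth, TreeBuf &buf) {
  const int n = hi - lo;
  double G = 0.0, H = 0.0;
  for (int i = lo; i < hi; ++i) { G += ctx.g[rows[i]]; H += ctx.h[rows[i]]; }

  const int id = (int)buf.feature.size();
  buf.feature.push_back(-1);
  buf.threshold.push_back(0.0);
  buf.left.push_back(-1);
  buf.right.push_back(-1);
  buf.value.push_back(H + ctx.lambda > 0 ? G / (H + ctx.lambda) : 0.0);

  if (depth >= ctx.max_depth || n < 2 * ctx.min_leaf) return id;

  const int p = ctx.B.ncol();
  int ntry = std::min(ctx.mtry, p);
  for (int j = 0; j < ntry; ++j) {
    int k = j + (int)std::floor(unif_rand() * (p - j));
    if (k >= p) k = p - 1;
    std::swap(ctx.feats[j], ctx.feats[k]);
  }

  double best_gain = 1e-12;
  int best_feat = -1, best_bin = -1;
  const double parent = (G * G) / (H + ctx.lambda);

  for (int jj = 0; jj < ntry; ++jj) {
    const int f = ctx.feats[jj];
    const int nb = (int)ctx.cuts[f].size() + 1;
    if (nb < 2) continue;
    std::fill(ctx.Gh.begin(), ctx.Gh.begin() + nb, 0.0);
    std::fill(ctx.Hh.begin(), ctx.Hh.begin() + nb, 0.0);
    std::fill(ctx.Ch.begin(), ctx.Ch.begin() + nb, 0);
    for (int i = lo; i < hi; ++i) {
      const int r = rows[i];
      const int b = ctx.B(r, f);
      ctx.Gh[b] += ctx.g[r];
      ctx.Hh[b] += ctx.h[r];
      ctx.Ch[b] += 1;
    }
    double GL = 0.0, HL = 0.0;
    int CL = 0;
    for (int b = 0; b + 1 < nb; ++b) {
      GL += ctx.Gh[b]; HL += ctx.Hh[b]; CL += ctx.Ch[b];
      if (CL < ctx.min_leaf || n - CL < ctx.min_leaf) continue;
      if (ctx.Ch[b] == 0) continue;  // no samples at this boundary
      const double GR = G - GL, HR = H - HL;
      if (HL < ctx.min_child_weight || HR < ctx.min_child_weight) continue;
      const double gain = GL * GL / (HL + ctx.lambda) +
                          GR * GR / (HR + ctx.lambda) - parent;
      if (gain > best_gain) {
        best_gain = gain;
        best_feat = f;
        best_bin = b;
      }
    }
  }

  if (best_feat < 0) return id;

  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (ctx.B(rows[i], best_feat) <= best_bin) std::swap(rows[i], rows[mid++]);
  if (mid == lo || mid == hi) return id;

  buf.feature[id] = best_feat;
  buf.threshold[id] = ctx.cuts[best_feat][best_bin];
  int l = grow_node(ctx, rows, lo, mid, depth + 1, buf);
  int r = grow_node(ctx, rows, mid, hi, depth + 1, buf);
  buf.left[id] = l;
  buf.right[id] = r;
  return id;
}

// [[Rcpp::export(name = ".tree_grow")]]
List tree_grow(IntegerMatrix binned, List cuts, NumericVector g,
               NumericVector h, IntegerVector row_idx, int max_depth,
               int min_leaf, double min_child_weight, int mtry,
               double lambda) {
  const int p = binned.ncol();
  std::vector<std::vector<double> > cutv(p);
  int nbins = 1;
  for (int j = 0; j < p; ++j) {
    NumericVector cj = cuts[j];
    cutv[j].assign(cj.begin(), cj.end());
    nbins = std::max(nbins, (int)cutv[j].size() + 1);
  }
  std::vector<double> gv(g.begin(), g.end()), hv(h.begin(), h.end());
  std::vector<int> rows(row_idx.begin(), row_idx.end()); // 0-based
  GrowCtx ctx(binned, cutv, gv, hv);
  ctx.max_depth = max_depth;
  ctx.min_leaf = min_leaf;
  ctx.min_child_weight = min_child_weight;
  ctx.mtry = mtry;
  ctx.lambda = lambda;
  ctx.nbins = nbins;
  ctx.Gh.resize(nbins);
  ctx.Hh.resize(nbins);
  ctx.Ch.resize(nbins);
  ctx.feats.resize(p);
  for (int j = 0; j < p; ++j) ctx.feats[j] = j;
  TreeBuf buf;
  RNGScope scope;
  grow_node(ctx, rows, 0, (int)rows.size(), 0, buf);
  return List::create(_["feature"] = wrap(buf.feature),
                      _["threshold"] = wrap(buf.threshold),
                      _["left"] = wrap(buf.left),
                      _["right"] = wrap(buf.right),
                      _["value"] = wrap(buf.value));
}

// [[Rcpp::export(name = ".tree_predict")]]
NumericVector tree_predict(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"];
  NumericVector threshold = tree["threshold"];
  IntegerVector left = tree["left"], right = tree["right"];
  NumericVector value = tree["value"];
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(i, feature[node]) <= threshold[node]) ? left[node] : right[node];
    }
    out[i] = value[node];
  }
  return out;
}

// Sliding-window summary statistics (mean, sd, min, max, median) over
// [t-w, t+w] clamped to the sequence. Frames flagged invalid are excluded
// from every window; the current frame is always included as a fallback so
// each output row is finite.
// [[Rcpp::export(name = ".window_stats")]]
NumericMatrix window_stats(NumericMatrix X, int w, LogicalVector valid) {
  const int n = X.nrow(), p = X.ncol();
  NumericMatrix out(n, 5 * p);
  std::vector<double> buf;
  buf.reserve(2 * w + 1);
  for (int j = 0; j < p; ++j) {
    for (int t = 0; t < n; ++t) {
      const int a = std::max(0, t - w), b = std::min(n - 1, t + w);
      buf.clear();
      for (int i = a; i <= b; ++i)
        if (valid[i] || i == t) buf.push_back(X(i, j));
      if (buf.empty()) buf.push_back(X(t, j));
      const int m = (int)buf.size();
      double s = 0.0, s2 = 0.0, mn = buf[0], mx = buf[0];
      for (int i = 0; i < m; ++i) {
        s += buf[i];
        if (buf[i] < mn) mn = buf[i];
        if (buf[i] > mx) mx = buf[i];
      }
      const double mean = s / m;
      for (int i = 0; i < m; ++i) s2 += (buf[i] - mean) * (buf[i] - mean);
      const double sd = m > 1 ? std::sqrt(s2 / (m - 1)) : 0.0;
      std::sort(buf.begin(), buf.end());
      const double med = (m % 2 == 1) ? buf[m / 2]
                                      : 0.5 * (buf[m / 2 - 1] + buf[m / 2]);
      out(t, j) = mean;
      out(t, p + j) = sd;
      out(t, 2 * p + j) = mn;
      out(t, 3 * p + j) = mx;
      out(t, 4 * p + j) = med;
    }
  }
  return out;
}
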
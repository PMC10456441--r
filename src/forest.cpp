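// Core of the surrogate random forest: weighted bootstrap, exhaustive
// midpoint Gini splits over mtry candidates, per-node surrogate splits
// scored by adjusted agreement, and OOB bookkeeping.  All randomness
// comes from a std::mt19937_64 stream seeded per tree from (seed, tree),
// so fits are reproducible independently of R's RNG state.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

// uniform double in [0, 1) with 53 random bits; avoids the
// implementation-defined std::uniform_real_distribution
inline double runif01(std::mt19937_64& gen) {
  return static_cast<double>(gen() >> 11) * (1.0 / 9007199254740992.0);
}

// uniform integer in [0, n)
inline int runif_int(std::mt19937_64& gen, int n) {
  return static_cast<int>(runif01(gen) * n) % n;
}

struct Surrogate {
  int var;      // 0-based
  double adj;   // adjusted agreement, > 0
  int dir;      // +1: x <= thr routes with primary-left; -1: reversed
};

struct Node {
  int depth = 0;
  int size = 0;          // in-bag size counting bootstrap multiplicity
  int split_var = -1;    // 0-based, -1 for leaf
  double threshold = 0.0;
  int left = -1, right = -1;
  int label = 0;         // majority class (0/1), defined for every node
  std::vector<Surrogate> surr;
};

struct BuildItem {
  int node_id;
  std::vector<int> samples;  // in-bag sample indices with multiplicity
};

inline double gini_decrease(int m, int c1, int nL, int nL1) {
  // parent impurity minus size-weighted child impurity, all unweighted
  // in-bag counts; c1 = parent class-1 count, nL1 = class-1 count left
  const double dm = m, dc1 = c1, dc0 = m - c1;
  const int nR = m - nL;
  const int nR1 = c1 - nL1;
  const double gP = 1.0 - (dc0 * dc0 + dc1 * dc1) / (dm * dm);
  const double dnL = nL, dnR = nR;
  const double gL =
      1.0 - (static_cast<double>(nL - nL1) * (nL - nL1) +
             static_cast<double>(nL1) * nL1) / (dnL * dnL);
  const double gR =
      1.0 - (static_cast<double>(nR - nR1) * (nR - nR1) +
             static_cast<double>(nR1) * nR1) / (dnR * dnR);
  return gP - (dnL / dm) * gL - (dnR / dm) * gR;
}

}  // namespace

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, NumericVector w,
                int ntree, int mtry, int min_node_size, int s_surr,
                int seed) {
  const int n = X.nrow();
  const int p = X.ncol();

  // global per-column sample order (ascending x, ties by index)
  std::vector<std::vector<int>> ord(p, std::vector<int>(n));
  for (int v = 0; v < p; ++v) {
    std::vector<int>& o = ord[v];
    for (int i = 0; i < n; ++i) o[i] = i;
    const double* col = &X(0, v);
    std::stable_sort(o.begin(), o.end(),
                     [col](int a, int b) { return col[a] < col[b]; });
  }

  std::vector<double> cumw(n);
  double tot = 0.0;
  for (int i = 0; i < n; ++i) {
    tot += w[i];
    cumw[i] = tot;
  }

  List trees(ntree);
  LogicalMatrix oob(ntree, n);
  IntegerMatrix inbag(ntree, n);

  std::vector<int> mult(n);       // node multiplicity per sample
  std::vector<int> route(n);      // 0 = primary-left, 1 = primary-right
  std::vector<int> varpool(p);

  for (int t = 0; t < ntree; ++t) {
    std::seed_seq ss{seed, t};
    std::mt19937_64 gen(ss);

    // weighted bootstrap: n draws with replacement, prob proportional to w
    std::vector<int> cnt(n, 0);
    for (int d = 0; d < n; ++d) {
      const double u = runif01(gen) * tot;
      int idx = static_cast<int>(
          std::lower_bound(cumw.begin(), cumw.end(), u) - cumw.begin());
      if (idx >= n) idx = n - 1;
      cnt[idx]++;
    }
    std::vector<int> root_samples;
    root_samples.reserve(n);
    for (int i = 0; i < n; ++i) {
      inbag(t, i) = cnt[i];
      oob(t, i) = (cnt[i] == 0);
      for (int r = 0; r < cnt[i]; ++r) root_samples.push_back(i);
    }

    std::vector<Node> nodes;
    nodes.reserve(2 * n);
    std::vector<BuildItem> stack;
    nodes.push_back(Node());
    nodes[0].depth = 0;
    stack.push_back({0, std::move(root_samples)});
    int max_depth = 0;

    while (!stack.empty()) {
      BuildItem item = std::move(stack.back());
      stack.pop_back();
      const int id = item.node_id;
      const std::vector<int>& smp = item.samples;
      const int m = static_cast<int>(smp.size());
      Node& nd = nodes[id];
      nd.size = m;

      int c1 = 0;
      for (int i : smp) c1 += y[i];
      const int c0 = m - c1;
      nd.label = (c1 > c0) ? 1 : 0;
      if (max_depth < nd.depth) max_depth = nd.depth;

      if (c0 == 0 || c1 == 0 || m <= min_node_size) continue;  // leaf

      std::fill(mult.begin(), mult.end(), 0);
      for (int i : smp) mult[i]++;

      // draw mtry distinct candidate variables (partial Fisher-Yates),
      // then evaluate in ascending index order so that equal impurity
      // decreases resolve to the lower variable index
      for (int v = 0; v < p; ++v) varpool[v] = v;
      const int ncand = std::min(mtry, p);
      for (int k = 0; k < ncand; ++k) {
        const int j = k + runif_int(gen, p - k);
        std::swap(varpool[k], varpool[j]);
      }
      std::sort(varpool.begin(), varpool.begin() + ncand);

      double best_dec = 0.0;
      int best_var = -1;
      double best_thr = 0.0;
      for (int k = 0; k < ncand; ++k) {
        const int v = varpool[k];
        const double* col = &X(0, v);
        int nL = 0, nL1 = 0;
        double x_prev = 0.0;
        bool have_prev = false;
        for (int oi = 0; oi < n; ++oi) {
          const int i = ord[v][oi];
          if (mult[i] == 0) continue;
          const double x = col[i];
          if (have_prev && x > x_prev && nL > 0 && nL < m) {
            const double dec = gini_decrease(m, c1, nL, nL1);
            if (dec > best_dec) {
              best_dec = dec;
              best_var = v;
              best_thr = 0.5 * (x_prev + x);
            }
          }
          nL += mult[i];
          nL1 += mult[i] * y[i];
          x_prev = x;
          have_prev = true;
        }
      }

      if (best_var < 0 || best_dec <= 0.0) continue;  // no usable split

      nd.split_var = best_var;
      nd.threshold = best_thr;

      // primary routing (0 = left) and child sample lists
      const double* pcol = &X(0, best_var);
      std::vector<int> left_s, right_s;
      left_s.reserve(m);
      right_s.reserve(m);
      int TL = 0;
      for (int i : smp) {
        if (pcol[i] <= best_thr) {
          left_s.push_back(i);
          TL++;
        } else {
          right_s.push_back(i);
        }
      }
      const int TR = m - TL;
      for (int i : smp) route[i] = (pcol[i] <= best_thr) ? 0 : 1;

      // surrogate search over every other variable; agreement of the
      // best mimicking split, direction reversal allowed
      const double mfrac = static_cast<double>(std::max(TL, TR)) / m;
      if (s_surr > 0 && mfrac < 1.0) {
        std::vector<Surrogate> cand;
        for (int j = 0; j < p; ++j) {
          if (j == best_var) continue;
          const double* col = &X(0, j);
          int cl = 0, cr = 0;  // primary-left / right mass routed left by j
          double x_prev = 0.0;
          bool have_prev = false;
          double bestA = -1.0;
          int bestDir = 1;
          for (int oi = 0; oi < n; ++oi) {
            const int i = ord[j][oi];
            if (mult[i] == 0) continue;
            const double x = col[i];
            if (have_prev && x > x_prev) {
              const int nl = cl + cr;
              if (nl > 0 && nl < m) {
                const int same = cl + (TR - cr);
                const int rev = cr + (TL - cl);
                double A;
                int dir;
                if (same >= rev) {
                  A = static_cast<double>(same) / m;
                  dir = 1;
                } else {
                  A = static_cast<double>(rev) / m;
                  dir = -1;
                }
                if (A > bestA) {
                  bestA = A;
                  bestDir = dir;
                }
              }
            }
            if (route[i] == 0)
              cl += mult[i];
            else
              cr += mult[i];
            x_prev = x;
            have_prev = true;
          }
          if (bestA > mfrac) {
            const double adj = (bestA - mfrac) / (1.0 - mfrac);
            cand.push_back({j, adj, bestDir});
          }
        }
        // top-s by adjusted agreement, ties to the lower variable index
        // (stable sort; candidates were generated in index order)
        std::stable_sort(cand.begin(), cand.end(),
                         [](const Surrogate& a, const Surrogate& b) {
                           return a.adj > b.adj;
                         });
        if (static_cast<int>(cand.size()) > s_surr) cand.resize(s_surr);
        nd.surr = std::move(cand);
      }

      const int left_id = static_cast<int>(nodes.size());
      nodes.push_back(Node());
      nodes[left_id].depth = nd.depth + 1;
      const int right_id = static_cast<int>(nodes.size());
      nodes.push_back(Node());
      nodes[right_id].depth = nd.depth + 1;
      // nd may be dangling after push_back; re-reference
      nodes[id].left = left_id;
      nodes[id].right = right_id;
      stack.push_back({right_id, std::move(right_s)});
      stack.push_back({left_id, std::move(left_s)});
    }

    const int nn = static_cast<int>(nodes.size());
    IntegerVector depth(nn), split_var(nn), left(nn), right(nn), label(nn),
        size(nn);
    NumericVector threshold(nn);
    List surr_var(nn), surr_adj(nn), surr_dir(nn);
    for (int i = 0; i < nn; ++i) {
      const Node& nd = nodes[i];
      depth[i] = nd.depth;
      split_var[i] = (nd.split_var < 0) ? 0 : nd.split_var + 1;
      threshold[i] = (nd.split_var < 0) ? NA_REAL : nd.threshold;
      left[i] = nd.left + 1;   // 0 = none
      right[i] = nd.right + 1;
      label[i] = nd.label + 1;  // 1-based class index
      size[i] = nd.size;
      const int ns = static_cast<int>(nd.surr.size());
      IntegerVector sv(ns), sd(ns);
      NumericVector sa(ns);
      for (int k = 0; k < ns; ++k) {
        sv[k] = nd.surr[k].var + 1;
        sa[k] = nd.surr[k].adj;
        sd[k] = nd.surr[k].dir;
      }
      surr_var[i] = sv;
      surr_adj[i] = sa;
      surr_dir[i] = sd;
    }
    trees[t] = List::create(
        Named("depth") = depth, Named("split_var") = split_var,
        Named("threshold") = threshold, Named("left") = left,
        Named("right") = right, Named("label") = label,
        Named("size") = size, Named("surr_var") = surr_var,
        Named("surr_adj") = surr_adj, Named("surr_dir") = surr_dir,
        Named("max_depth") = max_depth);
  }

  return List::create(Named("trees") = trees, Named("oob") = oob,
                      Named("inbag") = inbag);
}

// Route every row of X down every tree; returns an ntree x n matrix of
// 1-based class labels.
// [[Rcpp::export]]
IntegerMatrix rf_predict_cpp(List trees, NumericMatrix X) {
  const int ntree = trees.size();
  const int n = X.nrow();
  IntegerMatrix votes(ntree, n);
  for (int t = 0; t < ntree; ++t) {
    List tr = trees[t];
    IntegerVector split_var = tr["split_var"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"];
    IntegerVector right = tr["right"];
    IntegerVector label = tr["label"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (split_var[node] != 0) {
        const int v = split_var[node] - 1;
        node = (X(i, v) <= threshold[node]) ? left[node] - 1
                                            : right[node] - 1;
      }
      votes(t, i) = label[node];
    }
  }
  return votes;
}
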
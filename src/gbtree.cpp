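// Compact gradient-boosted regression trees with second-order (Newton)
// boosting: exact greedy split search, depth-limited level-wise growth,
// per-tree row/column subsampling, L1/L2 leaf regularization and gain-based
// feature importance. Logistic and squared-error objectives cover the
// classification and regression tasks of the prediction harness. Uses its
// own mt19937 stream so results are reproducible independently of R's RNG.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <random>
#include <vector>

namespace {

struct Node {
  int feature = -1;      // -1: leaf
  double threshold = 0.0;
  int left = -1, right = -1;
  double weight = 0.0;   // leaf value (already scaled by eta at predict time)
};

struct Tree {
  std::vector<Node> nodes;
  double predict(const double* x, int n, int nfeat) const {
    int i = 0;
    while (nodes[i].feature >= 0) {
      double v = x[static_cast<size_t>(nodes[i].feature) * n];
      i = (v < nodes[i].threshold) ? nodes[i].left : nodes[i].right;
    }
    return nodes[i].weight;
  }
};

// L1-thresholded numerator as in regularized leaf weight/gain.
inline double thresh_l1(double g, double alpha) {
  if (g > alpha) return g - alpha;
  if (g < -alpha) return g + alpha;
  return 0.0;
}

inline double calc_gain(double g, double h, double alpha, double lambda) {
  double t = thresh_l1(g, alpha);
  return t * t / (h + lambda);
}

inline double calc_weight(double g, double h, double alpha, double lambda) {
  return -thresh_l1(g, alpha) / (h + lambda);
}

} // namespace

// [[Rcpp::export(name = ".gbtree_fit_predict")]]
Rcpp::List gbtree_fit_predict(Rcpp::NumericMatrix Xtrain,
                              Rcpp::NumericVector y,
                              Rcpp::NumericMatrix Xtest,
                              std::string objective,
                              int nrounds, double eta, int max_depth,
                              double subsample, double colsample,
                              double lambda, double alpha,
                              double min_child_weight, int seed) {
  const int n = Xtrain.nrow(), p = Xtrain.ncol();
  const int ntest = Xtest.nrow();
  const bool logistic = (objective == "binary:logistic");
  std::mt19937 rng(static_cast<unsigned>(seed));

  // Presorted sample indices per feature (shared across trees).
  std::vector<std::vector<int>> order(p);
  for (int j = 0; j < p; ++j) {
    order[j].resize(n);
    for (int i = 0; i < n; ++i) order[j][i] = i;
    const double* col = &Xtrain(0, j);
    std::stable_sort(order[j].begin(), order[j].end(),
                     [col](int a, int b) { return col[a] < col[b]; });
  }

  double base_score = 0.0;
  if (!logistic) base_score = Rcpp::mean(y);
  std::vector<double> f(n, base_score);
  std::vector<double> grad(n), hess(n);
  std::vector<double> importance(p, 0.0);
  std::vector<Tree> trees;
  trees.reserve(nrounds);

  std::vector<int> node_of(n);          // node id per sample, -1 if unused
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  for (int round = 0; round < nrounds; ++round) {
    // gradients
    for (int i = 0; i < n; ++i) {
      if (logistic) {
        double pr = 1.0 / (1.0 + std::exp(-f[i]));
        grad[i] = pr - y[i];
        hess[i] = std::max(pr * (1.0 - pr), 1e-16);
      } else {
        grad[i] = f[i] - y[i];
        hess[i] = 1.0;
      }
    }

    // row subsample (without replacement)
    std::fill(node_of.begin(), node_of.end(), -1);
    if (subsample < 1.0) {
      int target = std::max(2, static_cast<int>(std::lround(subsample * n)));
      std::vector<int> idx(n);
      for (int i = 0; i < n; ++i) idx[i] = i;
      std::shuffle(idx.begin(), idx.end(), rng);
      for (int k = 0; k < target; ++k) node_of[idx[k]] = 0;
    } else {
      std::fill(node_of.begin(), node_of.end(), 0);
    }

    // column subsample
    std::vector<int> feats;
    for (int j = 0; j < p; ++j) {
      if (colsample >= 1.0 || unif(rng) < colsample) feats.push_back(j);
    }
    if (feats.empty()) feats.push_back(static_cast<int>(unif(rng) * p) % p);

    Tree tree;
    tree.nodes.emplace_back();
    std::vector<int> level_nodes{0};

    for (int depth = 0; depth < max_depth && !level_nodes.empty(); ++depth) {
      const int nnodes = static_cast<int>(tree.nodes.size());
      // node aggregates
      std::vector<double> Gtot(nnodes, 0.0), Htot(nnodes, 0.0);
      for (int i = 0; i < n; ++i) {
        if (node_of[i] >= 0) {
          Gtot[node_of[i]] += grad[i];
          Htot[node_of[i]] += hess[i];
        }
      }
      struct Best {
        double gain = 0.0; int feature = -1; double threshold = 0.0;
      };
      std::vector<Best> best(nnodes);
      std::vector<double> GL(nnodes), HL(nnodes), lastv(nnodes);
      std::vector<bool> seen(nnodes);

      for (int j : feats) {
        std::fill(GL.begin(), GL.end(), 0.0);
        std::fill(HL.begin(), HL.end(), 0.0);
        std::fill(seen.begin(), seen.end(), false);
        const double* col = &Xtrain(0, j);
        for (int pos = 0; pos < n; ++pos) {
          int i = order[j][pos];
          int nd = node_of[i];
          if (nd < 0) continue;
          double v = col[i];
          if (seen[nd] && v > lastv[nd]) {
            // candidate split between lastv and v
            double gl = GL[nd], hl = HL[nd];
            double gr = Gtot[nd] - gl, hr = Htot[nd] - hl;
            if (hl >= min_child_weight && hr >= min_child_weight) {
              double gain = 0.5 * (calc_gain(gl, hl, alpha, lambda) +
                                   calc_gain(gr, hr, alpha, lambda) -
                                   calc_gain(Gtot[nd], Htot[nd], alpha, lambda));
              if (gain > best[nd].gain + 1e-12) {
                best[nd].gain = gain;
                best[nd].feature = j;
                best[nd].threshold = 0.5 * (lastv[nd] + v);
              }
            }
          }
          GL[nd] += grad[i];
          HL[nd] += hess[i];
          lastv[nd] = v;
          seen[nd] = true;
        }
      }

      // apply best splits; collect next level
      std::vector<int> next_level;
      bool any_split = false;
      for (int nd : level_nodes) {
        if (best[nd].feature >= 0) {
          any_split = true;
          tree.nodes[nd].feature = best[nd].feature;
          tree.nodes[nd].threshold = best[nd].threshold;
          tree.nodes[nd].left = static_cast<int>(tree.nodes.size());
          tree.nodes.emplace_back();
          tree.nodes[nd].right = static_cast<int>(tree.nodes.size());
          tree.nodes.emplace_back();
          next_level.push_back(tree.nodes[nd].left);
          next_level.push_back(tree.nodes[nd].right);
          importance[best[nd].feature] += best[nd].gain;
        }
      }
      if (!any_split) break;
      for (int i = 0; i < n; ++i) {
        int nd = node_of[i];
        if (nd < 0) continue;
        const Node& noderef = tree.nodes[nd];
        if (noderef.feature >= 0) {
          node_of[i] = (Xtrain(i, noderef.feature) < noderef.threshold)
                         ? noderef.left : noderef.right;
        }
      }
      level_nodes = std::move(next_level);
    }

    // leaf weights
    {
      const int nnodes = static_cast<int>(tree.nodes.size());
      std::vector<double> Gtot(nnodes, 0.0), Htot(nnodes, 0.0);
      for (int i = 0; i < n; ++i) {
        if (node_of[i] >= 0) {
          Gtot[node_of[i]] += grad[i];
          Htot[node_of[i]] += hess[i];
        }
      }
      for (int k = 0; k < nnodes; ++k) {
        if (tree.nodes[k].feature < 0) {
          tree.nodes[k].weight =
              eta * calc_weight(Gtot[k], Htot[k], alpha, lambda);
        }
      }
    }

    // update ALL training scores (including out-of-bag rows)
    for (int i = 0; i < n; ++i) {
      f[i] += tree.predict(&Xtrain(i, 0), n, p);
    }
    trees.push_back(std::move(tree));
  }

  Rcpp::NumericVector pred_train(n), pred_test(ntest);
  for (int i = 0; i < n; ++i) pred_train[i] = f[i];
  for (int i = 0; i < ntest; ++i) {
    double s = base_score;
    for (const Tree& t : trees) s += t.predict(&Xtest(i, 0), ntest, p);
    pred_test[i] = s;
  }
  if (logistic) {
    for (int i = 0; i < n; ++i) pred_train[i] = 1.0 / (1.0 + std::exp(-pred_train[i]));
    for (int i = 0; i < ntest; ++i) pred_test[i] = 1.0 / (1.0 + std::exp(-pred_test[i]));
  }
  return Rcpp::List::create(
      Rcpp::Named("pred_train") = pred_train,
      Rcpp::Named("pred_test") = pred_test,
      Rcpp::Named("importance") = Rcpp::wrap(importance),
      Rcpp::Named("n_trees") = static_cast<int>(trees.size()));
}
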
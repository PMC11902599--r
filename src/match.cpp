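// Descriptor matching: exact two-nearest-neighbour search (blocked BLAS
// distance computation) and a FLANN-style approximate search over randomized
// kd-trees with a shared priority queue and a bounded leaf-check budget.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <queue>
#include <random>
#include <vector>
using namespace Rcpp;

// Exact: for each row of A, the two nearest rows of B (Euclidean).
// [[Rcpp::export]]
List cpp_match_bruteforce(const arma::mat& A, const arma::mat& B) {
  const arma::uword nA = A.n_rows, nB = B.n_rows;
  arma::vec b2 = arma::sum(arma::square(B), 1);
  IntegerVector best(nA);
  NumericVector d1(nA), d2(nA);
  const arma::uword blk = 512;
  for (arma::uword s = 0; s < nA; s += blk) {
    arma::uword e = std::min(s + blk, nA) - 1;
    arma::mat Ab = A.rows(s, e);
    arma::vec a2 = arma::sum(arma::square(Ab), 1);
    arma::mat D = -2.0 * (Ab * B.t());
    D.each_col() += a2;
    D.each_row() += b2.t();
    for (arma::uword i = 0; i < D.n_rows; ++i) {
      double m1 = arma::datum::inf, m2 = arma::datum::inf;
      arma::uword j1 = 0;
      for (arma::uword j = 0; j < nB; ++j) {
        double d = D(i, j);
        if (d < m1) { m2 = m1; m1 = d; j1 = j; }
        else if (d < m2) { m2 = d; }
      }
      best[s + i] = (int)j1 + 1;  // 1-based
      d1[s + i] = std::sqrt(std::max(m1, 0.0));
      d2[s + i] = std::sqrt(std::max(m2, 0.0));
    }
  }
  return List::create(_["idx"] = best, _["d1"] = d1, _["d2"] = d2);
}

namespace {

struct Node {
  int dim = -1;        // -1 marks a leaf
  double split = 0.0;
  int left = -1, right = -1;
  int start = 0, end = 0;  // leaf range into the index array
};

struct KdTree {
  std::vector<Node> nodes;
  std::vector<int> idx;
};

constexpr int LEAF_SIZE = 8;
constexpr int RAND_DIM_CANDIDATES = 5;

int build_node(KdTree& t, const arma::mat& B, int start, int end,
               std::mt19937& rng) {
  Node nd;
  int id = (int)t.nodes.size();
  t.nodes.push_back(nd);
  if (end - start <= LEAF_SIZE) {
    t.nodes[id].start = start;
    t.nodes[id].end = end;
    return id;
  }
  const int d = (int)B.n_cols;
  arma::vec mean(d, arma::fill::zeros), var(d, arma::fill::zeros);
  for (int i = start; i < end; ++i) mean += B.row(t.idx[i]).t();
  mean /= (end - start);
  for (int i = start; i < end; ++i) {
    arma::vec dv = B.row(t.idx[i]).t() - mean;
    var += arma::square(dv);
  }
  // split on a random choice among the highest-variance dimensions
  arma::uvec ord = arma::sort_index(var, "descend");
  int ncand = std::min(RAND_DIM_CANDIDATES, d);
  std::uniform_int_distribution<int> pick(0, ncand - 1);
  int dim = (int)ord[pick(rng)];
  double split = mean[dim];
  int mid = start;
  for (int i = start; i < end; ++i)
    if (B(t.idx[i], dim) < split) std::swap(t.idx[i], t.idx[mid++]);
  if (mid == start || mid == end) mid = start + (end - start) / 2;  // degenerate
  t.nodes[id].dim = dim;
  t.nodes[id].split = split;
  int l = build_node(t, B, start, mid, rng);
  int r = build_node(t, B, mid, end, rng);
  t.nodes[id].left = l;
  t.nodes[id].right = r;
  return id;
}

}  // namespace

// Approximate two-NN: `trees` randomized kd-trees searched jointly with a
// priority queue; at most max(checks, leaf visits to exhaustion) points are
// examined per query.  With checks >= nrow(B) the search is exhaustive and
// therefore exact.
// [[Rcpp::export]]
List cpp_match_kdtree(const arma::mat& A, const arma::mat& B, int trees,
                      int checks, int seed) {
  const int nA = (int)A.n_rows, nB = (int)B.n_rows;
  std::mt19937 rng((unsigned)seed);
  std::vector<KdTree> forest(trees);
  for (int t = 0; t < trees; ++t) {
    forest[t].idx.resize(nB);
    for (int i = 0; i < nB; ++i) forest[t].idx[i] = i;
    forest[t].nodes.reserve(2 * nB / LEAF_SIZE + 8);
    build_node(forest[t], B, 0, nB, rng);
  }
  IntegerVector best(nA);
  NumericVector d1o(nA), d2o(nA);
  std::vector<int> stamp(nB, -1);
  const bool exhaustive = checks >= nB;  // visit everything: exact search
  using QE = std::pair<double, std::pair<int, int>>;  // (bound, (tree, node))
  for (int q = 0; q < nA; ++q) {
    const arma::rowvec a = A.row(q);
    double m1 = arma::datum::inf, m2 = arma::datum::inf;
    int j1 = -1, nchecked = 0;
    std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;
    auto examine_leaf = [&](const KdTree& t, const Node& nd) {
      for (int i = nd.start; i < nd.end; ++i) {
        int j = t.idx[i];
        if (stamp[j] == q) continue;
        stamp[j] = q;
        ++nchecked;
        double d = arma::accu(arma::square(a - B.row(j)));
        if (d < m1) { m2 = m1; m1 = d; j1 = j; }
        else if (d < m2) { m2 = d; }
      }
    };
    auto descend = [&](const KdTree& t, int tree_id, int node_id, double bound) {
      int cur = node_id;
      double b = bound;
      while (t.nodes[cur].dim >= 0) {
        const Node& nd = t.nodes[cur];
        double diff = a[nd.dim] - nd.split;
        int near_id = diff < 0 ? nd.left : nd.right;
        int far_id = diff < 0 ? nd.right : nd.left;
        pq.push({b + diff * diff, {tree_id, far_id}});
        cur = near_id;
      }
      examine_leaf(t, t.nodes[cur]);
    };
    for (int t = 0; t < trees; ++t) descend(forest[t], t, 0, 0.0);
    while (nchecked < checks && !pq.empty()) {
      QE e = pq.top();
      pq.pop();
      // the accumulated bound is a heuristic; only prune on it when the
      // check budget makes the search approximate anyway
      if (!exhaustive && e.first >= m2) continue;
      descend(forest[e.second.first], e.second.first, e.second.second, e.first);
    }
    best[q] = j1 + 1;
    d1o[q] = std::sqrt(std::max(m1, 0.0));
    d2o[q] = std::sqrt(std::max(m2, 0.0));
  }
  return List::create(_["idx"] = best, _["d1"] = d1o, _["d2"] = d2o);
}
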
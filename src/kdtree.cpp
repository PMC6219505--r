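// 2-D kd-tree for nearest-neighbor (excluding self) distance queries.
// Median-split construction, branch-and-bound query; exact, so results are
// identical to exhaustive pairwise search.
#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Node {
  int point;       // index into the point arrays
  int axis;        // 0 = x, 1 = y
  int left, right; // children, -1 if absent
};

struct KDTree {
  const double *x, *y;
  std::vector<Node> nodes;
  int root;

  KDTree(const double *x_, const double *y_, int n) : x(x_), y(y_) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    nodes.reserve(n);
    root = build(idx.begin(), idx.end(), 0);
  }

  typedef std::vector<int>::iterator It;

  int build(It first, It last, int depth) {
    if (first == last) return -1;
    int axis = depth % 2;
    It mid = first + (last - first) / 2;
    const double *coord = axis == 0 ? x : y;
    std::nth_element(first, mid, last,
                     [coord](int a, int b) { return coord[a] < coord[b]; });
    Node nd;
    nd.point = *mid;
    nd.axis = axis;
    int self = (int)nodes.size();
    nodes.push_back(nd);
    int l = build(first, mid, depth + 1);
    int r = build(mid + 1, last, depth + 1);
    nodes[self].left = l;
    nodes[self].right = r;
    return self;
  }

  void query(int node, int q, double &best2) const {
    if (node < 0) return;
    const Node &nd = nodes[node];
    int p = nd.point;
    if (p != q) {
      double dx = x[p] - x[q], dy = y[p] - y[q];
      double d2 = dx * dx + dy * dy;
      if (d2 < best2) best2 = d2;
    }
    double diff = (nd.axis == 0) ? x[q] - x[nd.point] : y[q] - y[nd.point];
    int near = diff < 0 ? nd.left : nd.right;
    int far = diff < 0 ? nd.right : nd.left;
    query(near, q, best2);
    if (diff * diff < best2) query(far, q, best2);
  }
};

} // namespace

// [[Rcpp::export(name = ".kdtree_nn")]]
NumericVector kdtree_nn(NumericVector x, NumericVector y) {
  int n = x.size();
  if (n < 2) stop("need at least 2 points");
  KDTree tree(x.begin(), y.begin(), n);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best2 = R_PosInf;
    tree.query(tree.root, i, best2);
    out[i] = std::sqrt(best2);
  }
  return out;
}
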
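#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Static kd-tree over 3-D points in physical coordinates. Candidate distances
// are accumulated in the fixed order dz^2 + dy^2 + dx^2 so that results agree
// bit-for-bit with a plain exhaustive scan that uses the same expression.

namespace {

struct KdNode {
  int point;     // row index of the splitting point
  int axis;      // 0 = z, 1 = y, 2 = x
  int left, right;
};

struct KdTree {
  const double* pts;  // n x 3, column-major (z column, y column, x column)
  int n;
  std::vector<KdNode> nodes;
  std::vector<int> order;

  double coord(int i, int axis) const { return pts[axis * (R_xlen_t)n + i]; }

  int build(int lo, int hi, int depth) {
    if (lo >= hi) return -1;
    const int axis = depth % 3;
    const int mid = (lo + hi) / 2;
    std::nth_element(order.begin() + lo, order.begin() + mid,
                     order.begin() + hi, [&](int a, int b) {
                       return coord(a, axis) < coord(b, axis);
                     });
    KdNode node;
    node.point = order[mid];
    node.axis = axis;
    const int self = (int)nodes.size();
    nodes.push_back(node);
    nodes[self].left = build(lo, mid, depth + 1);
    nodes[self].right = build(mid + 1, hi, depth + 1);
    return self;
  }

  static double sqdist(const double* q, const double* p) {
    const double dz = q[0] - p[0];
    const double dy = q[1] - p[1];
    const double dx = q[2] - p[2];
    return dz * dz + dy * dy + dx * dx;
  }

  void query(int node, const double* q, int skip, double& best, int& best_i) const {
    if (node < 0) return;
    const KdNode& nd = nodes[node];
    const double p[3] = {coord(nd.point, 0), coord(nd.point, 1), coord(nd.point, 2)};
    if (nd.point != skip) {
      const double d2 = sqdist(q, p);
      if (d2 < best || (d2 == best && nd.point < best_i)) {
        best = d2;
        best_i = nd.point;
      }
    }
    const double diff = q[nd.axis] - p[nd.axis];
    const int near = diff <= 0 ? nd.left : nd.right;
    const int far = diff <= 0 ? nd.right : nd.left;
    query(near, q, skip, best, best_i);
    if (diff * diff <= best) query(far, q, skip, best, best_i);
  }
};

}  // namespace

// Nearest neighbour in `target` (m x 3 matrix, columns z,y,x in um) for each
// row of `query` (n x 3). If self_skip is TRUE the i-th query excludes the
// i-th target (tables must then be the same length). Returns distances (um)
// and 1-based indices of the nearest target row.
// [[Rcpp::export(name = ".kd_nearest")]]
List kd_nearest(NumericMatrix query, NumericMatrix target, bool self_skip) {
  const int n = query.nrow(), m = target.nrow();
  if (m < 1) stop("target point set is empty");
  if (self_skip && n != m)
    stop("self-exclusion requires query and target of equal size");

  KdTree tree;
  tree.pts = target.begin();
  tree.n = m;
  tree.order.resize(m);
  for (int i = 0; i < m; ++i) tree.order[i] = i;
  tree.nodes.reserve(m);
  const int root = tree.build(0, m, 0);

  NumericVector dist(n);
  IntegerVector idx(n);
  for (int i = 0; i < n; ++i) {
    const double q[3] = {query(i, 0), query(i, 1), query(i, 2)};
    double best = R_PosInf;
    int best_i = -1;
    tree.query(root, q, self_skip ? i : -1, best, best_i);
    if (best_i < 0) stop("no admissible nearest neighbour (single self-excluded point?)");
    dist[i] = std::sqrt(best);
    idx[i] = best_i + 1;
  }
  return List::create(_["distance"] = dist, _["index"] = idx);
}
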
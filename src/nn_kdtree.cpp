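#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

// kd-tree over the reference set, built once per query batch.
// Points are stored in an index array that is recursively partitioned by
// nth_element around the median along the cycling split dimension, so the
// tree is balanced and needs no explicit node allocation.

namespace {

struct KDTree {
  const double *pts;   // column-major N x dim (R matrix layout)
  int n, dim;
  std::vector<int> idx;

  KDTree(const double *p, int n_, int dim_) : pts(p), n(n_), dim(dim_), idx(n_) {
    for (int i = 0; i < n; ++i) idx[i] = i;
    build(0, n, 0);
  }

  double coord(int i, int d) const { return pts[i + (size_t)d * n]; }

  void build(int lo, int hi, int depth) {
    if (hi - lo <= 1) return;
    int mid = (lo + hi) / 2;
    int d = depth % dim;
    std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                     [&](int a, int b) { return coord(a, d) < coord(b, d); });
    build(lo, mid, depth + 1);
    build(mid + 1, hi, depth + 1);
  }

  void query(const double *q, int lo, int hi, int depth, double &best2) const {
    if (lo >= hi) return;
    int mid = (lo + hi) / 2;
    int i = idx[mid];
    double d2 = 0.0;
    for (int d = 0; d < dim; ++d) {
      double diff = q[d] - coord(i, d);
      d2 += diff * diff;
    }
    if (d2 < best2) best2 = d2;
    int sd = depth % dim;
    double delta = q[sd] - coord(i, sd);
    int nearLo = (delta < 0) ? lo : mid + 1;
    int nearHi = (delta < 0) ? mid : hi;
    int farLo = (delta < 0) ? mid + 1 : lo;
    int farHi = (delta < 0) ? hi : mid;
    query(q, nearLo, nearHi, depth + 1, best2);
    if (delta * delta < best2) query(q, farLo, farHi, depth + 1, best2);
  }
};

} // namespace

// [[Rcpp::export(name = ".nn_query_cpp")]]
Rcpp::NumericVector nn_query_cpp(Rcpp::NumericMatrix query,
                                 Rcpp::NumericMatrix ref) {
  int dim = ref.ncol();
  if (query.ncol() != dim) Rcpp::stop("dimension mismatch");
  if (ref.nrow() == 0) Rcpp::stop("empty reference set");
  KDTree tree(ref.begin(), ref.nrow(), dim);
  int nq = query.nrow();
  Rcpp::NumericVector out(nq);
  std::vector<double> q(dim);
  for (int i = 0; i < nq; ++i) {
    for (int d = 0; d < dim; ++d) q[d] = query(i, d);
    double best2 = R_PosInf;
    tree.query(q.data(), 0, tree.n, 0, best2);
    out[i] = std::sqrt(best2);
  }
  return out;
}
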
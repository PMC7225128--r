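#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Brute-force k-nearest-neighbor indices (1-based) of each query row among
// the reference rows, for arbitrary dimensionality. The 2-D hot paths use
// the kd-tree below instead.
// [[Rcpp::export]]
IntegerMatrix cpp_knn_brute(NumericMatrix ref, NumericMatrix query, int k) {
  const int n = ref.nrow(), m = query.nrow(), d = ref.ncol();
  if (k < 1 || k > n) stop("k out of range");
  IntegerMatrix out(m, k);
  std::vector<std::pair<double, int> > cand(n);
  for (int q = 0; q < m; ++q) {
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int j = 0; j < d; ++j) {
        double diff = ref(i, j) - query(q, j);
        s += diff * diff;
      }
      cand[i] = std::make_pair(s, i);
    }
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
    for (int j = 0; j < k; ++j) out(q, j) = cand[j].second + 1;
  }
  return out;
}

// Mean of `values` rows over each query's k nearest reference rows.
// [[Rcpp::export]]
NumericMatrix cpp_knn_mean(NumericMatrix ref, NumericMatrix query,
                           NumericMatrix values, int k) {
  IntegerMatrix idx = cpp_knn_brute(ref, query, k);
  const int m = query.nrow(), p = values.ncol();
  NumericMatrix out(m, p);
  for (int q = 0; q < m; ++q) {
    for (int j = 0; j < k; ++j) {
      int i = idx(q, j) - 1;
      for (int c = 0; c < p; ++c) out(q, c) += values(i, c);
    }
    for (int c = 0; c < p; ++c) out(q, c) /= k;
  }
  return out;
}

namespace {

// Static 2-D kd-tree with leaf buckets; O(k log n) queries independent of
// the density structure of the reference set (dense clusters, sparse gaps,
// and queries far outside the cloud all behave).
struct KDTree2D {
  struct Node {
    int axis;        // -1 for leaf
    double split;
    int left, right; // children (internal nodes)
    int beg, end;    // point range (leaves)
  };
  std::vector<Node> nodes;
  std::vector<int> order;
  std::vector<double> px, py;
  int n;

  void build(const NumericMatrix &pts) {
    n = pts.nrow();
    px.resize(n); py.resize(n);
    for (int i = 0; i < n; ++i) { px[i] = pts(i, 0); py[i] = pts(i, 1); }
    order.resize(n);
    for (int i = 0; i < n; ++i) order[i] = i;
    nodes.clear();
    nodes.reserve(2 * n / 8 + 4);
    build_range(0, n);
  }

  int build_range(int beg, int end) {
    int id = (int)nodes.size();
    nodes.push_back(Node());
    if (end - beg <= 16) {
      nodes[id].axis = -1; nodes[id].beg = beg; nodes[id].end = end;
      return id;
    }
    double xmin = px[order[beg]], xmax = xmin, ymin = py[order[beg]], ymax = ymin;
    for (int i = beg + 1; i < end; ++i) {
      xmin = std::min(xmin, px[order[i]]); xmax = std::max(xmax, px[order[i]]);
      ymin = std::min(ymin, py[order[i]]); ymax = std::max(ymax, py[order[i]]);
    }
    int axis = (xmax - xmin >= ymax - ymin) ? 0 : 1;
    int mid = (beg + end) / 2;
    const std::vector<double> &coord = axis == 0 ? px : py;
    std::nth_element(order.begin() + beg, order.begin() + mid,
                     order.begin() + end,
                     [&](int a, int b) { return coord[a] < coord[b]; });
    nodes[id].axis = axis;
    nodes[id].split = coord[order[mid]];
    int l = build_range(beg, mid);
    int r = build_range(mid, end);
    nodes[id].left = l;
    nodes[id].right = r;
    return id;
  }

  // max-heap of (dist2, index) pairs, size <= k
  void search(int node, double qx, double qy, int k,
              std::vector<std::pair<double, int> > &heap) const {
    const Node &nd = nodes[node];
    if (nd.axis == -1) {
      for (int i = nd.beg; i < nd.end; ++i) {
        int p = order[i];
        double dx = px[p] - qx, dy = py[p] - qy;
        double d2 = dx * dx + dy * dy;
        if ((int)heap.size() < k) {
          heap.push_back(std::make_pair(d2, p));
          std::push_heap(heap.begin(), heap.end());
        } else if (d2 < heap.front().first ||
                   (d2 == heap.front().first && p < heap.front().second)) {
          std::pop_heap(heap.begin(), heap.end());
          heap.back() = std::make_pair(d2, p);
          std::push_heap(heap.begin(), heap.end());
        }
      }
      return;
    }
    double qc = nd.axis == 0 ? qx : qy;
    double diff = qc - nd.split;
    int near = diff <= 0 ? nd.left : nd.right;
    int far = diff <= 0 ? nd.right : nd.left;
    search(near, qx, qy, k, heap);
    if ((int)heap.size() < k || diff * diff <= heap.front().first) {
      search(far, qx, qy, k, heap);
    }
  }

  // k nearest indices, ties broken by index order; scratch reused
  void knn(double qx, double qy, int k,
           std::vector<std::pair<double, int> > &scratch) const {
    scratch.clear();
    search(0, qx, qy, std::min(k, n), scratch);
    std::sort(scratch.begin(), scratch.end());
  }
};

}  // namespace

// kd-tree kNN indices for 2-D reference sets; brute force otherwise.
// [[Rcpp::export]]
IntegerMatrix cpp_knn_query(NumericMatrix ref, NumericMatrix query, int k) {
  if (ref.ncol() != 2) return cpp_knn_brute(ref, query, k);
  const int n = ref.nrow(), m = query.nrow();
  if (k < 1 || k > n) stop("k out of range");
  KDTree2D tree;
  tree.build(ref);
  IntegerMatrix out(m, k);
  std::vector<std::pair<double, int> > scratch;
  scratch.reserve(k + 1);
  for (int q = 0; q < m; ++q) {
    tree.knn(query(q, 0), query(q, 1), k, scratch);
    for (int j = 0; j < k; ++j) out(q, j) = scratch[j].second + 1;
  }
  return out;
}

// Explicit-Euler phase-point simulation through a kNN velocity field.
// cells, vel: n x d reference positions and velocities; init: m x d start
// positions. Each step moves every point by step_size times the mean
// velocity of its k nearest reference cells, plus N(0, noise_sd) jitter per
// coordinate (drawn from R's RNG, so set.seed() controls it). Positions at
// steps 0, record_stride, 2*record_stride, ... are recorded. A density
// histogram over a grid_nx x grid_ny grid spanning [xlim, ylim] counts
// point-visits in the first two coordinates at every step.
// [[Rcpp::export]]
List cpp_phase_sim(NumericMatrix cells, NumericMatrix vel, NumericMatrix init,
                   int n_steps, int k, double step_size, double noise_sd,
                   int record_stride, int grid_nx, int grid_ny,
                   NumericVector xlim, NumericVector ylim) {
  const int n = cells.nrow(), m = init.nrow(), d = cells.ncol();
  if (vel.nrow() != n || vel.ncol() != d || init.ncol() != d)
    stop("dimension mismatch between cells, velocities, and init positions");
  if (k < 1 || k > n) stop("k_field out of range for this group");
  const bool use_tree = (d == 2);
  KDTree2D tree;
  if (use_tree) tree.build(cells);

  std::vector<double> pos(init.begin(), init.end());  // column-major m x d
  int n_rec = n_steps / record_stride + 1;
  NumericVector traj(Dimension(m, n_rec, d));
  IntegerVector rec_steps(n_rec);
  NumericMatrix density(grid_nx, grid_ny);
  double gx0 = xlim[0], gy0 = ylim[0];
  double ghx = (xlim[1] - xlim[0]) / grid_nx, ghy = (ylim[1] - ylim[0]) / grid_ny;
  if (ghx <= 0) ghx = 1;
  if (ghy <= 0) ghy = 1;

  std::vector<std::pair<double, int> > scratch(n);
  scratch.reserve(n);
  std::vector<double> v(d);

  int rec = 0;
  for (int step = 0; step <= n_steps; ++step) {
    if (step % record_stride == 0) {
      for (int c = 0; c < d; ++c)
        for (int i = 0; i < m; ++i)
          traj[i + (R_xlen_t)m * rec + (R_xlen_t)m * n_rec * c] =
            pos[i + (R_xlen_t)m * c];
      rec_steps[rec] = step;
      ++rec;
    }
    for (int i = 0; i < m; ++i) {
      int bx = (int)((pos[i] - gx0) / ghx);
      int by = (int)((pos[i + (R_xlen_t)m] - gy0) / ghy);
      if (bx >= 0 && bx < grid_nx && by >= 0 && by < grid_ny)
        density(bx, by) += 1.0;
    }
    if (step == n_steps) break;
    for (int i = 0; i < m; ++i) {
      std::fill(v.begin(), v.end(), 0.0);
      int kk = k;
      if (use_tree) {
        // unsorted neighbor set suffices for the mean
        scratch.clear();
        tree.search(0, pos[i], pos[i + (R_xlen_t)m], std::min(k, n), scratch);
        kk = (int)scratch.size();
        for (int j = 0; j < kk; ++j) {
          int r = scratch[j].second;
          v[0] += vel(r, 0);
          v[1] += vel(r, 1);
        }
      } else {
        scratch.resize(n);
        for (int r = 0; r < n; ++r) {
          double s = 0.0;
          for (int c = 0; c < d; ++c) {
            double diff = cells(r, c) - pos[i + (R_xlen_t)m * c];
            s += diff * diff;
          }
          scratch[r] = std::make_pair(s, r);
        }
        std::partial_sort(scratch.begin(), scratch.begin() + k, scratch.end());
        for (int j = 0; j < k; ++j)
          for (int c = 0; c < d; ++c) v[c] += vel(scratch[j].second, c);
      }
      for (int c = 0; c < d; ++c) {
        double dz = step_size * v[c] / kk;
        if (noise_sd > 0) dz += noise_sd * norm_rand();
        pos[i + (R_xlen_t)m * c] += dz;
      }
    }
  }

  NumericMatrix terminal(m, d);
  for (int c = 0; c < d; ++c)
    for (int i = 0; i < m; ++i) terminal(i, c) = pos[i + (R_xlen_t)m * c];
  return List::create(_["trajectories"] = traj,
                      _["rec_steps"] = rec_steps,
                      _["terminal"] = terminal,
                      _["density"] = density);
}
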
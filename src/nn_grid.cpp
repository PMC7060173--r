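// Uniform-grid spatial index for 2D point sets.
//
// Supports the two queries the 2-CLASTA statistics need:
//   * mean distance to the k nearest reference points (plain Euclidean),
//   * number of reference points within a fixed radius (disc counts).
// Batched variants re-use one index across the N toroidal-shift
// randomizations, which dominates the cost of a test run.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

class PointGrid {
public:
  PointGrid(const NumericVector& rx, const NumericVector& ry) {
    n_ = rx.size();
    px_.assign(rx.begin(), rx.end());
    py_.assign(ry.begin(), ry.end());
    double xmin = px_[0], xmax = px_[0], ymin = py_[0], ymax = py_[0];
    for (int i = 1; i < n_; ++i) {
      xmin = std::min(xmin, px_[i]); xmax = std::max(xmax, px_[i]);
      ymin = std::min(ymin, py_[i]); ymax = std::max(ymax, py_[i]);
    }
    double w = std::max(xmax - xmin, 1e-9);
    double h = std::max(ymax - ymin, 1e-9);
    // target ~2 points per occupied cell
    double ncell = std::max(1.0, n_ / 2.0);
    double aspect = w / h;
    nx_ = std::max(1, (int)std::lround(std::sqrt(ncell * aspect)));
    ny_ = std::max(1, (int)std::lround(std::sqrt(ncell / aspect)));
    x0_ = xmin; y0_ = ymin;
    cw_ = w / nx_; ch_ = h / ny_;
    std::vector<int> cell(n_);
    start_.assign((size_t)nx_ * ny_ + 1, 0);
    for (int i = 0; i < n_; ++i) {
      int cx = clampi((int)std::floor((px_[i] - x0_) / cw_), 0, nx_ - 1);
      int cy = clampi((int)std::floor((py_[i] - y0_) / ch_), 0, ny_ - 1);
      cell[i] = cy * nx_ + cx;
      ++start_[cell[i] + 1];
    }
    for (size_t c = 1; c < start_.size(); ++c) start_[c] += start_[c - 1];
    order_.resize(n_);
    std::vector<int> cursor(start_.begin(), start_.end() - 1);
    for (int i = 0; i < n_; ++i) order_[cursor[cell[i]]++] = i;
  }

  // mean of the k smallest Euclidean distances from (qx, qy) to the set
  double meanKnn(double qx, double qy, int k, std::vector<double>& heap) const {
    heap.clear();
    // clamp the center cell into the grid: for an outside query the true
    // index distance to any cell is >= the clamped one, so the ring lower
    // bound below stays valid
    int cx = cellIndex(qx, x0_, cw_, nx_);
    int cy = cellIndex(qy, y0_, ch_, ny_);
    double mincell = std::min(cw_, ch_);
    int dmax = std::max(std::max(std::abs(cx), std::abs(cx - (nx_ - 1))),
                        std::max(std::abs(cy), std::abs(cy - (ny_ - 1))));
    for (int d = 0; d <= dmax; ++d) {
      if ((int)heap.size() == k && d >= 1) {
        double bound = (double)(d - 1) * mincell;
        if (bound * bound > heap.front()) break;
      }
      if (d == 0) {
        scanCell(cx, cy, qx, qy, k, heap);
      } else {
        for (int i = cx - d; i <= cx + d; ++i) {
          scanCell(i, cy - d, qx, qy, k, heap);
          scanCell(i, cy + d, qx, qy, k, heap);
        }
        for (int j = cy - d + 1; j <= cy + d - 1; ++j) {
          scanCell(cx - d, j, qx, qy, k, heap);
          scanCell(cx + d, j, qx, qy, k, heap);
        }
      }
    }
    double s = 0.0;
    for (double d2 : heap) s += std::sqrt(d2);
    return s / k;
  }

  // number of points within radius r of (qx, qy)
  int discCount(double qx, double qy, double r) const {
    double r2 = r * r;
    int cxlo = cellIndex(qx - r, x0_, cw_, nx_);
    int cxhi = cellIndex(qx + r, x0_, cw_, nx_);
    int cylo = cellIndex(qy - r, y0_, ch_, ny_);
    int cyhi = cellIndex(qy + r, y0_, ch_, ny_);
    int cnt = 0;
    for (int cy = cylo; cy <= cyhi; ++cy) {
      for (int cx = cxlo; cx <= cxhi; ++cx) {
        int c = cy * nx_ + cx;
        for (int j = start_[c]; j < start_[c + 1]; ++j) {
          int i = order_[j];
          double dx = px_[i] - qx, dy = py_[i] - qy;
          if (dx * dx + dy * dy <= r2) ++cnt;
        }
      }
    }
    return cnt;
  }

private:
  static int clampi(int v, int lo, int hi) {
    return v < lo ? lo : (v > hi ? hi : v);
  }

  // clamped cell index, computed in double space so far-outside queries
  // cannot overflow the int cast
  static int cellIndex(double q, double orig, double cell, int ncell) {
    double t = std::floor((q - orig) / cell);
    if (t < 0) return 0;
    if (t > ncell - 1) return ncell - 1;
    return (int)t;
  }

  void scanCell(int cx, int cy, double qx, double qy, int k,
                std::vector<double>& heap) const {
    if (cx < 0 || cx >= nx_ || cy < 0 || cy >= ny_) return;
    int c = cy * nx_ + cx;
    for (int j = start_[c]; j < start_[c + 1]; ++j) {
      int i = order_[j];
      double dx = px_[i] - qx, dy = py_[i] - qy;
      double d2 = dx * dx + dy * dy;
      if ((int)heap.size() < k) {
        heap.push_back(d2);
        std::push_heap(heap.begin(), heap.end());
      } else if (d2 < heap.front()) {
        std::pop_heap(heap.begin(), heap.end());
        heap.back() = d2;
        std::push_heap(heap.begin(), heap.end());
      }
    }
  }

  int n_, nx_, ny_;
  double x0_, y0_, cw_, ch_;
  std::vector<double> px_, py_;
  std::vector<int> start_, order_;
};

inline double wrap(double v, double lo, double span) {
  double t = (v - lo) / span;
  double w = (t - std::floor(t)) * span;
  if (w >= span) w = 0.0;  // guard against rounding at the top edge
  return w + lo;
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_cross_knn(NumericVector qx, NumericVector qy,
                            NumericVector rx, NumericVector ry, int k) {
  if (rx.size() < k) stop("reference set has fewer than k points");
  PointGrid grid(rx, ry);
  int nq = qx.size();
  NumericVector out(nq);
  std::vector<double> heap;
  heap.reserve(k + 1);
  for (int i = 0; i < nq; ++i) {
    out[i] = grid.meanKnn(qx[i], qy[i], k, heap);
    if ((i & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Distances for the observed pair plus each toroidally shifted query set.
// Element 1 of the result is the unshifted query; element i+1 applies
// shift (sx[i], sy[i]) with wrap-around on [xmin, xmax) x [ymin, ymax).
// [[Rcpp::export]]
List cpp_clasta_knn(NumericVector qx, NumericVector qy,
                    NumericVector rx, NumericVector ry, int k,
                    NumericVector sx, NumericVector sy,
                    double xmin, double ymin, double xmax, double ymax) {
  if (rx.size() < k) stop("reference set has fewer than k points");
  PointGrid grid(rx, ry);
  int nq = qx.size(), ns = sx.size();
  double w = xmax - xmin, h = ymax - ymin;
  List out(ns + 1);
  std::vector<double> heap;
  heap.reserve(k + 1);
  {
    NumericVector d(nq);
    for (int i = 0; i < nq; ++i) d[i] = grid.meanKnn(qx[i], qy[i], k, heap);
    out[0] = d;
  }
  for (int s = 0; s < ns; ++s) {
    NumericVector d(nq);
    for (int i = 0; i < nq; ++i) {
      double x = wrap(qx[i] + sx[s], xmin, w);
      double y = wrap(qy[i] + sy[s], ymin, h);
      d[i] = grid.meanKnn(x, y, k, heap);
    }
    out[s + 1] = d;
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_disc_counts(NumericVector qx, NumericVector qy,
                              NumericVector rx, NumericVector ry,
                              double rstar) {
  PointGrid grid(rx, ry);
  int nq = qx.size();
  IntegerVector out(nq);
  for (int i = 0; i < nq; ++i) {
    out[i] = grid.discCount(qx[i], qy[i], rstar);
    if ((i & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Disc counts for the observed pair plus each toroidally shifted query set.
// [[Rcpp::export]]
List cpp_clasta_disc(NumericVector qx, NumericVector qy,
                     NumericVector rx, NumericVector ry, double rstar,
                     NumericVector sx, NumericVector sy,
                     double xmin, double ymin, double xmax, double ymax) {
  PointGrid grid(rx, ry);
  int nq = qx.size(), ns = sx.size();
  double w = xmax - xmin, h = ymax - ymin;
  List out(ns + 1);
  {
    IntegerVector c(nq);
    for (int i = 0; i < nq; ++i) c[i] = grid.discCount(qx[i], qy[i], rstar);
    out[0] = c;
  }
  for (int s = 0; s < ns; ++s) {
    IntegerVector c(nq);
    for (int i = 0; i < nq; ++i) {
      double x = wrap(qx[i] + sx[s], xmin, w);
      double y = wrap(qy[i] + sy[s], ymin, h);
      c[i] = grid.discCount(x, y, rstar);
    }
    out[s + 1] = c;
    Rcpp::checkUserInterrupt();
  }
  return out;
}
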
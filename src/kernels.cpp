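#include <Rcpp.h>
#include <queue>
#include <utility>
#include <cmath>
using namespace Rcpp;

// Matrices follow the package's image convention: element (r, c) is the
// pixel at 0-based coordinates x = c, y = r.  All coordinates passed in
// from R are 0-based.

static const double TWO_PI = 2.0 * M_PI;

// Gradient-orientation histogram around (x, y) in a circular window of
// the given radius, magnitudes weighted by a Gaussian of std sigma_w.
// Gradients use the unit-spacing central differences
//   dx = L(x+1, y) - L(x-1, y),  dy = L(x, y+1) - L(x, y-1)
// (y pointing down the rows), direction atan2(dy, dx) mapped to [0, 2pi).
// [[Rcpp::export]]
NumericVector cpp_orientation_hist(const NumericMatrix& L, double x, double y,
                                   double sigma_w, double radius, int nbins) {
  NumericVector hist(nbins);
  int h = L.nrow(), w = L.ncol();
  int cx = (int)std::lround(x), cy = (int)std::lround(y);
  int r = (int)std::ceil(radius);
  double r2 = radius * radius;
  double denom = 2.0 * sigma_w * sigma_w;
  for (int dy_ = -r; dy_ <= r; ++dy_) {
    int yy = cy + dy_;
    if (yy < 1 || yy > h - 2) continue;
    for (int dx_ = -r; dx_ <= r; ++dx_) {
      int xx = cx + dx_;
      if (xx < 1 || xx > w - 2) continue;
      double dd = (double)dx_ * dx_ + (double)dy_ * dy_;
      if (dd > r2) continue;
      double gx = L(yy, xx + 1) - L(yy, xx - 1);
      double gy = L(yy + 1, xx) - L(yy - 1, xx);
      double m = std::sqrt(gx * gx + gy * gy);
      if (m <= 0.0) continue;
      double th = std::atan2(gy, gx);
      if (th < 0.0) th += TWO_PI;
      int b = (int)std::floor(th / TWO_PI * nbins);
      if (b >= nbins) b = nbins - 1;
      hist[b] += m * std::exp(-dd / denom);
    }
  }
  return hist;
}

// Raw (unnormalised) d x d x norient gradient histogram of the rotated,
// Gaussian-weighted window around an oriented keypoint, with trilinear
// interpolation across the two spatial cell axes and orientation.
// hist_width = side length of one spatial cell in pixels (3*sigma);
// the sampling radius gets the sqrt(2) rotation slack.
// Returns a vector of length d*d*norient ordered (orientation fastest,
// then column cell, then row cell); attribute "n_used" = pixels used.
// [[Rcpp::export]]
NumericVector cpp_descriptor_raw(const NumericMatrix& L, double x, double y,
                                 double hist_width, double theta_rad,
                                 int d, int norient, double win_sigma_cells) {
  NumericVector out(d * d * norient);
  int h = L.nrow(), w = L.ncol();
  double ct = std::cos(theta_rad), st = std::sin(theta_rad);
  double radius = hist_width * M_SQRT2 * (d + 1) * 0.5;
  int r = (int)std::ceil(radius);
  double denom = 2.0 * win_sigma_cells * win_sigma_cells;
  int cx = (int)std::lround(x), cy = (int)std::lround(y);
  int used = 0;
  for (int i = -r; i <= r; ++i) {
    int yy = cy + i;
    if (yy < 1 || yy > h - 2) continue;
    for (int j = -r; j <= r; ++j) {
      int xx = cx + j;
      if (xx < 1 || xx > w - 2) continue;
      double dx_ = xx - x, dy_ = yy - y;
      // rotate into the keypoint frame (by -theta) and scale to cell units
      double xr = (ct * dx_ + st * dy_) / hist_width;
      double yr = (-st * dx_ + ct * dy_) / hist_width;
      double cbin = xr + d / 2.0 - 0.5;
      double rbin = yr + d / 2.0 - 0.5;
      if (cbin <= -1.0 || cbin >= d || rbin <= -1.0 || rbin >= d) continue;
      double gx = L(yy, xx + 1) - L(yy, xx - 1);
      double gy = L(yy + 1, xx) - L(yy - 1, xx);
      double m = std::sqrt(gx * gx + gy * gy);
      if (m <= 0.0) continue;
      double th = std::atan2(gy, gx) - theta_rad;
      while (th < 0.0) th += TWO_PI;
      while (th >= TWO_PI) th -= TWO_PI;
      double obin = th / TWO_PI * norient;
      double wgt = m * std::exp(-(xr * xr + yr * yr) / denom);
      ++used;
      int r0 = (int)std::floor(rbin), c0 = (int)std::floor(cbin),
          o0 = (int)std::floor(obin);
      double fr = rbin - r0, fc = cbin - c0, fo = obin - o0;
      for (int dr = 0; dr <= 1; ++dr) {
        int rr = r0 + dr;
        if (rr < 0 || rr >= d) continue;
        double wr = wgt * (dr ? fr : 1.0 - fr);
        for (int dc = 0; dc <= 1; ++dc) {
          int cc = c0 + dc;
          if (cc < 0 || cc >= d) continue;
          double wc = wr * (dc ? fc : 1.0 - fc);
          for (int dob = 0; dob <= 1; ++dob) {
            int oo = (o0 + dob) % norient;
            double wo = wc * (dob ? fo : 1.0 - fo);
            out[(rr * d + cc) * norient + oo] += wo;
          }
        }
      }
    }
  }
  out.attr("n_used") = used;
  return out;
}

// ---- nearest-neighbour search -------------------------------------------

// candidate (d2, idx) better than incumbent (bd2, bidx)?
static inline bool nn_better(double d2, int idx, double bd2, int bidx) {
  return d2 < bd2 || (d2 == bd2 && idx < bidx);
}

static inline void nn_update(double d2, int idx, double& d1s, int& i1,
                             double& d2s, int& i2) {
  if (nn_better(d2, idx, d1s, i1)) {
    d2s = d1s; i2 = i1;
    d1s = d2; i1 = idx;
  } else if (nn_better(d2, idx, d2s, i2)) {
    d2s = d2; i2 = idx;
  }
}

// Exact 2-NN by full scan, ascending-index ties-to-lower.  Rows of `data`
// are the stored descriptors; one result row per row of `queries`:
// (i1, i2, d1, d2) with 1-based indices and Euclidean distances.
// [[Rcpp::export]]
NumericMatrix cpp_brute_knn2(const NumericMatrix& data,
                             const NumericMatrix& queries) {
  int n = data.nrow(), dim = data.ncol(), m = queries.nrow();
  NumericMatrix res(m, 4);
  for (int qi = 0; qi < m; ++qi) {
    double d1s = R_PosInf, d2s = R_PosInf;
    int i1 = -1, i2 = -1;
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int j = 0; j < dim; ++j) {
        double diff = data(i, j) - queries(qi, j);
        s += diff * diff;
      }
      nn_update(s, i, d1s, i1, d2s, i2);
    }
    res(qi, 0) = i1 + 1;
    res(qi, 1) = i2 + 1;
    res(qi, 2) = std::sqrt(d1s);
    res(qi, 3) = std::sqrt(d2s);
  }
  return res;
}

// Best-bin-first 2-NN over a flattened KD-tree.  Node arrays are 1-based
// (0 = no child); leaves carry point[node] > 0.  The priority queue is
// keyed on a lower bound of the distance from the query to the node's
// region (axis distance to the farther half-space); the search stops when
// the queue empties or `budget` leaves have been examined.  Pruning uses
// a strict inequality so an unlimited budget reproduces brute force
// exactly, including equal-distance tie-breaks.
// [[Rcpp::export]]
NumericMatrix cpp_bbf_knn2(const IntegerVector& split_dim,
                           const NumericVector& split_val,
                           const IntegerVector& left,
                           const IntegerVector& right,
                           const IntegerVector& point,
                           const NumericMatrix& data,
                           const NumericMatrix& queries,
                           double budget) {
  int dim = data.ncol(), m = queries.nrow();
  NumericMatrix res(m, 5);
  typedef std::pair<double, int> QE;  // (key, node)
  for (int qi = 0; qi < m; ++qi) {
    std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
    pq.push(QE(0.0, 1));
    double d1s = R_PosInf, d2s = R_PosInf;
    int i1 = -1, i2 = -1;
    int leaves = 0;
    while (!pq.empty()) {
      QE top = pq.top(); pq.pop();
      double key = top.first;
      int node = top.second;
      if (i2 >= 0 && key * key > d2s) continue;  // cannot improve
      int pt = point[node - 1];
      if (pt > 0) {  // leaf
        if (leaves >= budget) break;
        ++leaves;
        double s = 0.0;
        for (int j = 0; j < dim; ++j) {
          double diff = data(pt - 1, j) - queries(qi, j);
          s += diff * diff;
        }
        nn_update(s, pt - 1, d1s, i1, d2s, i2);
      } else {
        int sd = split_dim[node - 1] - 1;
        double axis_d = queries(qi, sd) - split_val[node - 1];
        int near = axis_d <= 0 ? left[node - 1] : right[node - 1];
        int far = axis_d <= 0 ? right[node - 1] : left[node - 1];
        double far_key = std::fabs(axis_d);
        if (far_key < key) far_key = key;
        if (near > 0) pq.push(QE(key, near));
        if (far > 0) pq.push(QE(far_key, far));
      }
    }
    res(qi, 0) = i1 + 1;
    res(qi, 1) = i2 + 1;
    res(qi, 2) = std::sqrt(d1s);
    res(qi, 3) = std::sqrt(d2s);
    res(qi, 4) = leaves;
  }
  return res;
}
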
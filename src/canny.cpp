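#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

static inline int reflect(int i, int n) {
  if (i < 0) i = -i - 1;
  if (i >= n) i = 2 * n - i - 1;
  if (i < 0) i = 0;
  if (i >= n) i = n - 1;
  return i;
}

// separable Gaussian blur with reflective borders
// [[Rcpp::export]]
NumericMatrix gauss_blur_cpp(const NumericMatrix& img, double sigma) {
  int nr = img.nrow(), nc = img.ncol();
  if (sigma <= 0) return clone(img);
  int rad = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * rad + 1);
  double s = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + rad];
  }
  for (double& v : k) v /= s;

  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int c = 0; c < nc; ++c)       // vertical pass
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      for (int i = -rad; i <= rad; ++i) acc += k[i + rad] * img(reflect(r + i, nr), c);
      tmp(r, c) = acc;
    }
  for (int r = 0; r < nr; ++r)       // horizontal pass
    for (int c = 0; c < nc; ++c) {
      double acc = 0.0;
      for (int i = -rad; i <= rad; ++i) acc += k[i + rad] * tmp(r, reflect(c + i, nc));
      out(r, c) = acc;
    }
  return out;
}

// Canny edge detector: Gaussian smoothing, Sobel gradients, non-maximum
// suppression quantized to 4 directions, double-threshold hysteresis (8-conn).
// low/high are thresholds on gradient magnitude.
// [[Rcpp::export]]
LogicalMatrix canny_cpp(const NumericMatrix& gray, double low, double high,
                        double sigma = 1.4) {
  int nr = gray.nrow(), nc = gray.ncol();
  NumericMatrix sm = gauss_blur_cpp(gray, sigma);

  NumericMatrix mag(nr, nc);
  IntegerMatrix dir(nr, nc);
  for (int r = 1; r < nr - 1; ++r) {
    for (int c = 1; c < nc - 1; ++c) {
      double gx = (sm(r - 1, c + 1) + 2 * sm(r, c + 1) + sm(r + 1, c + 1)) -
                  (sm(r - 1, c - 1) + 2 * sm(r, c - 1) + sm(r + 1, c - 1));
      double gy = (sm(r + 1, c - 1) + 2 * sm(r + 1, c) + sm(r + 1, c + 1)) -
                  (sm(r - 1, c - 1) + 2 * sm(r - 1, c) + sm(r - 1, c + 1));
      mag(r, c) = std::sqrt(gx * gx + gy * gy);
      double ang = std::atan2(gy, gx);           // [-pi, pi]
      double deg = ang * 180.0 / M_PI;
      if (deg < 0) deg += 180.0;
      int d;
      if (deg < 22.5 || deg >= 157.5) d = 0;     // horizontal gradient -> E/W nbrs
      else if (deg < 67.5) d = 1;                // diagonal
      else if (deg < 112.5) d = 2;               // vertical gradient -> N/S nbrs
      else d = 3;
      dir(r, c) = d;
    }
  }

  LogicalMatrix strong(nr, nc), weak(nr, nc);
  static const int dr[4] = {0, 1, 1, 1};
  static const int dc[4] = {1, 1, 0, -1};
  for (int r = 1; r < nr - 1; ++r)
    for (int c = 1; c < nc - 1; ++c) {
      double m = mag(r, c);
      if (m < low) continue;
      int d = dir(r, c);
      double m1 = mag(r + dr[d], c + dc[d]);
      double m2 = mag(r - dr[d], c - dc[d]);
      if (m >= m1 && m >= m2) {
        if (m >= high) strong(r, c) = true; else weak(r, c) = true;
      }
    }

  // hysteresis: keep weak edges 8-connected to strong ones
  LogicalMatrix out(nr, nc);
  std::queue<std::pair<int, int> > q;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      if (strong(r, c)) { out(r, c) = true; q.push(std::make_pair(r, c)); }
  while (!q.empty()) {
    std::pair<int, int> p = q.front(); q.pop();
    for (int i = -1; i <= 1; ++i)
      for (int j = -1; j <= 1; ++j) {
        int rr = p.first + i, cc = p.second + j;
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (weak(rr, cc) && !out(rr, cc)) {
          out(rr, cc) = true;
          q.push(std::make_pair(rr, cc));
        }
      }
  }
  return out;
}

// Sobel gradient field of the Gaussian-smoothed image; used for the
// radial-consistency check in the circle detector.
// [[Rcpp::export]]
List sobel_cpp(const NumericMatrix& gray, double sigma = 1.4) {
  int nr = gray.nrow(), nc = gray.ncol();
  NumericMatrix sm = gauss_blur_cpp(gray, sigma);
  NumericMatrix gx(nr, nc), gy(nr, nc);
  for (int r = 1; r < nr - 1; ++r)
    for (int c = 1; c < nc - 1; ++c) {
      gx(r, c) = (sm(r - 1, c + 1) + 2 * sm(r, c + 1) + sm(r + 1, c + 1)) -
                 (sm(r - 1, c - 1) + 2 * sm(r, c - 1) + sm(r + 1, c - 1));
      gy(r, c) = (sm(r + 1, c - 1) + 2 * sm(r + 1, c) + sm(r + 1, c + 1)) -
                 (sm(r - 1, c - 1) + 2 * sm(r - 1, c) + sm(r - 1, c + 1));
    }
  return List::create(_["gx"] = gx, _["gy"] = gy);
}
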
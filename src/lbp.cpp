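#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Rotation-invariant uniform LBP histogram (riu2), P sampling points on a
// circle of radius R, bilinear interpolation. Bins 0..P = uniform patterns by
// number of ones, bin P+1 = non-uniform. Pixels are counted only when the
// centre and all bilinear support pixels of all P samples lie inside `mask`.
// Returns raw counts (length P + 2); normalization happens in R.
// [[Rcpp::export]]
NumericVector lbp_hist_cpp(const NumericMatrix& gray, const LogicalMatrix& mask,
                           int P = 16, double R = 2.0) {
  int nr = gray.nrow(), nc = gray.ncol();
  NumericVector hist(P + 2);
  std::vector<double> dx(P), dy(P);
  for (int p = 0; p < P; ++p) {
    double a = 2.0 * M_PI * p / P;
    dx[p] = R * std::cos(a);
    dy[p] = -R * std::sin(a);
  }
  std::vector<int> s(P);
  int rad = (int)std::ceil(R);
  for (int r = rad; r < nr - rad; ++r) {
    for (int c = rad; c < nc - rad; ++c) {
      if (!mask(r, c)) continue;
      double gc = gray(r, c);
      bool ok = true;
      for (int p = 0; p < P && ok; ++p) {
        double y = r + dy[p], x = c + dx[p];
        int y0 = (int)std::floor(y), x0 = (int)std::floor(x);
        int y1 = y0 + 1, x1 = x0 + 1;
        if (y0 < 0 || x0 < 0 || y1 >= nr || x1 >= nc ||
            !mask(y0, x0) || !mask(y0, x1) || !mask(y1, x0) || !mask(y1, x1)) {
          ok = false;
          break;
        }
        double fy = y - y0, fx = x - x0;
        double g = gray(y0, x0) * (1 - fy) * (1 - fx) + gray(y0, x1) * (1 - fy) * fx +
                   gray(y1, x0) * fy * (1 - fx) + gray(y1, x1) * fy * fx;
        s[p] = (g - gc >= -1e-6) ? 1 : 0;   // epsilon absorbs bilinear FP noise
      }
      if (!ok) continue;
      int ones = 0, trans = 0;
      for (int p = 0; p < P; ++p) {
        ones += s[p];
        trans += std::abs(s[p] - s[(p + 1) % P]);
      }
      int bin = (trans <= 2) ? ones : (P + 1);
      hist[bin] += 1.0;
    }
  }
  return hist;
}
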
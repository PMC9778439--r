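#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Rectangular dilation; kernel kh x kw, anchored at centre (floor division).
// [[Rcpp::export]]
LogicalMatrix dilate_rect_cpp(const LogicalMatrix& m, int kh, int kw) {
  int nr = m.nrow(), nc = m.ncol();
  int ah = kh / 2, aw = kw / 2;
  LogicalMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      if (!m(r, c)) continue;
      int r0 = std::max(0, r - ah), r1 = std::min(nr - 1, r + (kh - 1 - ah));
      int c0 = std::max(0, c - aw), c1 = std::min(nc - 1, c + (kw - 1 - aw));
      for (int rr = r0; rr <= r1; ++rr)
        for (int cc = c0; cc <= c1; ++cc) out(rr, cc) = true;
    }
  return out;
}

// [[Rcpp::export]]
LogicalMatrix erode_rect_cpp(const LogicalMatrix& m, int kh, int kw) {
  int nr = m.nrow(), nc = m.ncol();
  int ah = kh / 2, aw = kw / 2;
  LogicalMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      bool all = true;
      for (int i = 0; i < kh && all; ++i)
        for (int j = 0; j < kw && all; ++j) {
          int rr = r + i - ah, cc = c + j - aw;
          // outside the image counts as background (erosion shrinks at borders)
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc || !m(rr, cc)) all = false;
        }
      out(r, c) = all;
    }
  return out;
}

// Connected-component labelling, conn in {4, 8}; labels from 1, 0 = background.
// [[Rcpp::export]]
List label_cpp(const LogicalMatrix& m, int conn = 8) {
  int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<std::pair<int, int> > nbr;
  nbr.push_back(std::make_pair(-1, 0)); nbr.push_back(std::make_pair(1, 0));
  nbr.push_back(std::make_pair(0, -1)); nbr.push_back(std::make_pair(0, 1));
  if (conn == 8) {
    nbr.push_back(std::make_pair(-1, -1)); nbr.push_back(std::make_pair(-1, 1));
    nbr.push_back(std::make_pair(1, -1)); nbr.push_back(std::make_pair(1, 1));
  }
  std::queue<std::pair<int, int> > q;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      if (!m(r, c) || lab(r, c)) continue;
      ++next;
      lab(r, c) = next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        std::pair<int, int> p = q.front(); q.pop();
        for (size_t k = 0; k < nbr.size(); ++k) {
          int rr = p.first + nbr[k].first, cc = p.second + nbr[k].second;
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (m(rr, cc) && !lab(rr, cc)) {
            lab(rr, cc) = next;
            q.push(std::make_pair(rr, cc));
          }
        }
      }
    }
  return List::create(_["labels"] = lab, _["n"] = next);
}

// Fill holes: background 4-connected to the border stays background,
// everything else becomes foreground.
// [[Rcpp::export]]
LogicalMatrix fill_holes_cpp(const LogicalMatrix& m) {
  int nr = m.nrow(), nc = m.ncol();
  LogicalMatrix reach(nr, nc);
  std::queue<std::pair<int, int> > q;
  for (int r = 0; r < nr; ++r) {
    if (!m(r, 0) && !reach(r, 0)) { reach(r, 0) = true; q.push(std::make_pair(r, 0)); }
    if (!m(r, nc - 1) && !reach(r, nc - 1)) { reach(r, nc - 1) = true; q.push(std::make_pair(r, nc - 1)); }
  }
  for (int c = 0; c < nc; ++c) {
    if (!m(0, c) && !reach(0, c)) { reach(0, c) = true; q.push(std::make_pair(0, c)); }
    if (!m(nr - 1, c) && !reach(nr - 1, c)) { reach(nr - 1, c) = true; q.push(std::make_pair(nr - 1, c)); }
  }
  static const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  while (!q.empty()) {
    std::pair<int, int> p = q.front(); q.pop();
    for (int k = 0; k < 4; ++k) {
      int rr = p.first + dr[k], cc = p.second + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (!m(rr, cc) && !reach(rr, cc)) { reach(rr, cc) = true; q.push(std::make_pair(rr, cc)); }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) out(r, c) = m(r, c) || !reach(r, c);
  return out;
}

// Moore-neighbour outer-boundary tracing of component `id` in a label image.
// Returns an N x 2 matrix of 0-based (x = col, y = row) boundary coordinates,
// clockwise, with Jacob's stopping criterion.
// [[Rcpp::export]]
IntegerMatrix trace_contour_cpp(const IntegerMatrix& lab, int id) {
  int nr = lab.nrow(), nc = lab.ncol();
  int sr = -1, sc = -1;
  for (int r = 0; r < nr && sr < 0; ++r)
    for (int c = 0; c < nc; ++c)
      if (lab(r, c) == id) { sr = r; sc = c; break; }
  if (sr < 0) return IntegerMatrix(0, 2);

  // Moore neighbourhood in clockwise order starting West
  static const int mr[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  static const int mc[8] = {-1, -1, 0, 1, 1, 1, 0, -1};

  std::vector<int> xs, ys;
  // state = (current pixel, backtrack direction index pointing at the
  // background pixel we came past); stop when the initial state recurs.
  int cr = sr, cc = sc;
  int bt = 0;                     // backtrack points West (row-major entry)
  int cr0 = cr, cc0 = cc, bt0 = bt;
  xs.push_back(cc); ys.push_back(cr);
  bool moved = false;
  for (int guard = 0; guard < 8 * nr * nc + 8; ++guard) {
    int found = -1, prev = bt;
    for (int k = 1; k <= 8; ++k) {
      int idx = (bt + k) % 8;
      int rr = cr + mr[idx], ccol = cc + mc[idx];
      if (rr >= 0 && rr < nr && ccol >= 0 && ccol < nc && lab(rr, ccol) == id) {
        found = idx;
        break;
      }
      prev = idx;
    }
    if (found < 0) break;         // isolated pixel
    int nr_ = cr + mr[found], nc_ = cc + mc[found];
    // backtrack for the new pixel: direction from new pixel to `prev` position
    int pr = cr + mr[prev], pc = cc + mc[prev];
    int dbr = pr - nr_, dbc = pc - nc_;
    int nbt = -1;
    for (int k = 0; k < 8; ++k)
      if (mr[k] == dbr && mc[k] == dbc) { nbt = k; break; }
    if (nbt < 0) nbt = (found + 4) % 8;   // defensive; prev is 8-adjacent in practice
    cr = nr_; cc = nc_; bt = nbt;
    if (moved && cr == cr0 && cc == cc0 && bt == bt0) break;
    if (cr == cr0 && cc == cc0 && guard > 8 * nr * nc) break;
    if (!(cr == cr0 && cc == cc0)) { xs.push_back(cc); ys.push_back(cr); }
    moved = true;
  }
  IntegerMatrix out(xs.size(), 2);
  for (size_t i = 0; i < xs.size(); ++i) { out(i, 0) = xs[i]; out(i, 1) = ys[i]; }
  return out;
}
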
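#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Binary-image primitives for seed masks. Pixels are matrix cells; outside the
// image is background. Connectivity conventions: 4-connected components,
// 8-connected boundary (see package docs).

static inline bool inb(int i, int j, int nr, int nc) {
  return i >= 0 && i < nr && j >= 0 && j < nc;
}

// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(const LogicalMatrix& m) {
  const int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  const int di[4] = {-1, 1, 0, 0};
  const int dj[4] = {0, 0, -1, 1};
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!m(i, j) || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front(); q.pop();
        for (int k = 0; k < 4; ++k) {
          int ni = p.first + di[k], nj = p.second + dj[k];
          if (inb(ni, nj, nr, nc) && m(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            q.push(std::make_pair(ni, nj));
          }
        }
      }
    }
  }
  return lab;
}

// Fill interior holes: background cells not 4-connected to the image border
// become foreground.
// [[Rcpp::export(name = ".fill_holes")]]
LogicalMatrix fill_holes(const LogicalMatrix& m) {
  const int nr = m.nrow(), nc = m.ncol();
  LogicalMatrix out(nr, nc);
  std::vector<char> outside((size_t) nr * nc, 0);
  std::queue<std::pair<int, int> > q;
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      bool border = (i == 0 || j == 0 || i == nr - 1 || j == nc - 1);
      if (border && !m(i, j) && !outside[(size_t) j * nr + i]) {
        outside[(size_t) j * nr + i] = 1;
        q.push(std::make_pair(i, j));
      }
    }
  }
  const int di[4] = {-1, 1, 0, 0};
  const int dj[4] = {0, 0, -1, 1};
  while (!q.empty()) {
    std::pair<int, int> p = q.front(); q.pop();
    for (int k = 0; k < 4; ++k) {
      int ni = p.first + di[k], nj = p.second + dj[k];
      if (inb(ni, nj, nr, nc) && !m(ni, nj) && !outside[(size_t) nj * nr + ni]) {
        outside[(size_t) nj * nr + ni] = 1;
        q.push(std::make_pair(ni, nj));
      }
    }
  }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = m(i, j) || !outside[(size_t) j * nr + i];
  return out;
}

// 3x3 square structuring element.
// [[Rcpp::export(name = ".dilate3")]]
LogicalMatrix dilate3(const LogicalMatrix& m) {
  const int nr = m.nrow(), nc = m.ncol();
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      bool v = false;
      for (int dj = -1; dj <= 1 && !v; ++dj)
        for (int di = -1; di <= 1 && !v; ++di) {
          int ni = i + di, nj = j + dj;
          if (inb(ni, nj, nr, nc) && m(ni, nj)) v = true;
        }
      out(i, j) = v;
    }
  return out;
}

// [[Rcpp::export(name = ".erode3")]]
LogicalMatrix erode3(const LogicalMatrix& m) {
  const int nr = m.nrow(), nc = m.ncol();
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      bool v = true;
      for (int dj = -1; dj <= 1 && v; ++dj)
        for (int di = -1; di <= 1 && v; ++di) {
          int ni = i + di, nj = j + dj;
          if (!inb(ni, nj, nr, nc) || !m(ni, nj)) v = false;
        }
      out(i, j) = v;
    }
  return out;
}

// Mask pixels with at least one background neighbour (conn = 4 or 8).
// [[Rcpp::export(name = ".border_pixels")]]
LogicalMatrix border_pixels(const LogicalMatrix& m, int conn) {
  const int nr = m.nrow(), nc = m.ncol();
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!m(i, j)) { out(i, j) = false; continue; }
      bool b = false;
      for (int dj = -1; dj <= 1 && !b; ++dj)
        for (int di = -1; di <= 1 && !b; ++di) {
          if (di == 0 && dj == 0) continue;
          if (conn == 4 && di != 0 && dj != 0) continue;
          int ni = i + di, nj = j + dj;
          if (!inb(ni, nj, nr, nc) || !m(ni, nj)) b = true;
        }
      out(i, j) = b;
    }
  return out;
}

// Moore-neighbour boundary trace of a single 4-connected, hole-free object.
// Returns the closed 8-connected chain length, diagonal steps weighted
// sqrt(2). Single-pixel objects return 1 by convention so the perimeter of a
// non-empty mask is always positive.
// [[Rcpp::export(name = ".boundary_chain_length")]]
double boundary_chain_length(const LogicalMatrix& m) {
  const int nr = m.nrow(), nc = m.ncol();
  long area = 0;
  int si = -1, sj = -1;
  for (int i = 0; i < nr && si < 0; ++i)
    for (int j = 0; j < nc; ++j)
      if (m(i, j)) { si = i; sj = j; break; }
  if (si < 0) stop("empty mask");
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (m(i, j)) ++area;
  if (area == 1) return 1.0;
  // clockwise neighbour order starting west (row index increases downward)
  const int di[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  const int dj[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  // start pixel is leftmost of the topmost row; its west neighbour is
  // background, so backtrack direction 0 (west) is valid
  int ci = si, cj = sj, back = 0;
  double len = 0.0;
  long steps = 0;
  const long maxsteps = 16L * area + 64L;
  int first_move = -1;
  while (steps < maxsteps) {
    int found = -1;
    for (int k = 1; k <= 8; ++k) {
      int idx = (back + k) % 8;
      int ni = ci + di[idx], nj = cj + dj[idx];
      if (inb(ni, nj, nr, nc) && m(ni, nj)) { found = idx; break; }
    }
    if (found < 0) break;  // isolated pixel (cannot happen for area > 1)
    bool diag = (di[found] != 0 && dj[found] != 0);
    len += diag ? std::sqrt(2.0) : 1.0;
    // backtrack points from the new pixel towards the previous one; the
    // clockwise search then resumes at the neighbour just past it
    back = (found + 4) % 8;
    ci += di[found];
    cj += dj[found];
    ++steps;
    if (first_move < 0) first_move = found;
    else if (ci == si && cj == sj) {
      // closed: peek at the next move; stop when it repeats the first move
      int nxt = -1;
      for (int k = 1; k <= 8; ++k) {
        int idx = (back + k) % 8;
        int ni = ci + di[idx], nj = cj + dj[idx];
        if (inb(ni, nj, nr, nc) && m(ni, nj)) { nxt = idx; break; }
      }
      if (nxt == first_move) break;
    }
  }
  return len;
}
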
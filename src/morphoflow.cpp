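#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Arrays follow R's column-major layout with dim = c(ny, nx, nz):
// linear index = y + ny * (x + nx * z), all 0-based.

// Zero-mean normalized cross-correlation of a (wy,wx,wz) template against a
// (wy+2my, wx+2mx, wz+2mz) search block, for every integer lag in
// [-m, +m] per axis. Returns a (2my+1, 2mx+1, 2mz+1) correlation cube.
// Search-block window sums come from 3D summed-area tables so the inner
// loop is a single multiply-accumulate per voxel.
// [[Rcpp::export]]
NumericVector cpp_zncc_cube(NumericVector a, NumericVector b,
                            int wy, int wx, int wz,
                            int my, int mx, int mz) {
  const int by = wy + 2 * my, bx = wx + 2 * mx, bz = wz + 2 * mz;
  if ((int)a.size() != wy * wx * wz) stop("template size mismatch");
  if ((int)b.size() != by * bx * bz) stop("search block size mismatch");
  const double n = (double)wy * wx * wz;

  // center the template once
  std::vector<double> ca(a.size());
  double amean = 0.0;
  for (double v : a) amean += v;
  amean /= n;
  double ass = 0.0;
  for (int i = 0; i < (int)a.size(); ++i) {
    ca[i] = a[i] - amean;
    ass += ca[i] * ca[i];
  }

  // summed-area tables for b and b^2, dims (by+1, bx+1, bz+1)
  const int sy = by + 1, sx = bx + 1;
  std::vector<double> S((size_t)sy * sx * (bz + 1), 0.0);
  std::vector<double> S2((size_t)sy * sx * (bz + 1), 0.0);
  auto sidx = [&](int y, int x, int z) -> size_t {
    return (size_t)y + (size_t)sy * ((size_t)x + (size_t)sx * z);
  };
  for (int z = 1; z <= bz; ++z)
    for (int x = 1; x <= bx; ++x)
      for (int y = 1; y <= by; ++y) {
        double v = b[(y - 1) + by * ((x - 1) + bx * (z - 1))];
        double c = v
          + S[sidx(y - 1, x, z)] + S[sidx(y, x - 1, z)] + S[sidx(y, x, z - 1)]
          - S[sidx(y - 1, x - 1, z)] - S[sidx(y - 1, x, z - 1)] - S[sidx(y, x - 1, z - 1)]
          + S[sidx(y - 1, x - 1, z - 1)];
        S[sidx(y, x, z)] = c;
        double c2 = v * v
          + S2[sidx(y - 1, x, z)] + S2[sidx(y, x - 1, z)] + S2[sidx(y, x, z - 1)]
          - S2[sidx(y - 1, x - 1, z)] - S2[sidx(y - 1, x, z - 1)] - S2[sidx(y, x - 1, z - 1)]
          + S2[sidx(y - 1, x - 1, z - 1)];
        S2[sidx(y, x, z)] = c2;
      }
  auto boxsum = [&](std::vector<double>& T, int y0, int x0, int z0) -> double {
    // sum over [y0, y0+wy) x [x0, x0+wx) x [z0, z0+wz)
    int y1 = y0 + wy, x1 = x0 + wx, z1 = z0 + wz;
    return T[sidx(y1, x1, z1)] - T[sidx(y0, x1, z1)] - T[sidx(y1, x0, z1)]
         - T[sidx(y1, x1, z0)] + T[sidx(y0, x0, z1)] + T[sidx(y0, x1, z0)]
         + T[sidx(y1, x0, z0)] - T[sidx(y0, x0, z0)];
  };

  const int ly = 2 * my + 1, lx = 2 * mx + 1, lz = 2 * mz + 1;
  NumericVector out(ly * lx * lz);
  out.attr("dim") = IntegerVector::create(ly, lx, lz);

  for (int oz = 0; oz < lz; ++oz)
    for (int ox = 0; ox < lx; ++ox)
      for (int oy = 0; oy < ly; ++oy) {
        double num = 0.0;
        for (int z = 0; z < wz; ++z)
          for (int x = 0; x < wx; ++x) {
            const double* bp = &b[(oy) + by * ((x + ox) + bx * (z + oz))];
            const double* ap = &ca[(size_t)0 + wy * ((size_t)x + (size_t)wx * z)];
            for (int y = 0; y < wy; ++y) num += ap[y] * bp[y];
          }
        double sb = boxsum(S, oy, ox, oz);
        double sb2 = boxsum(S2, oy, ox, oz);
        double bss = sb2 - sb * sb / n;
        double denom = ass * bss;
        double r = 0.0;
        if (denom > 0.0) r = num / std::sqrt(denom);
        out[oy + ly * (ox + lx * oz)] = r;
      }
  return out;
}

// Separable Gaussian blur of a matrix, reflect-101 boundary.
// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur2d(NumericMatrix img, double sigma) {
  int ny = img.nrow(), nx = img.ncol();
  if (sigma <= 0) return clone(img);
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double ks = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    ks += k[i + r];
  }
  for (double& v : k) v /= ks;
  auto refl = [](int i, int n) {
    while (i < 0 || i >= n) {
      if (i < 0) i = -i;
      if (i >= n) i = 2 * n - 2 - i;
    }
    return i;
  };
  NumericMatrix tmp(ny, nx), out(ny, nx);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      double s = 0.0;
      for (int i = -r; i <= r; ++i) s += k[i + r] * img(refl(y + i, ny), x);
      tmp(y, x) = s;
    }
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      double s = 0.0;
      for (int i = -r; i <= r; ++i) s += k[i + r] * tmp(y, refl(x + i, nx));
      out(y, x) = s;
    }
  return out;
}

// Separable running min/max (van Herk) with window 2r+1 along rows then
// columns: grayscale erosion/dilation with a (2r+1) square structuring
// element in O(1) per pixel. Out-of-image samples are ignored.
static void runmm1d(const std::vector<double>& in, std::vector<double>& out,
                    int n, int r, bool mn) {
  std::vector<int> dq(n);
  int head = 0, tailq = 0;
  for (int i = 0; i < n + r; ++i) {
    if (i < n) {
      while (tailq > head &&
             (mn ? in[dq[tailq - 1]] >= in[i] : in[dq[tailq - 1]] <= in[i]))
        --tailq;
      dq[tailq++] = i;
    }
    int left = i - 2 * r;
    while (tailq > head && dq[head] < left) ++head;
    if (i >= r) out[i - r] = in[dq[head]];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_minmax_box2d(NumericMatrix img, int r, bool erode) {
  int ny = img.nrow(), nx = img.ncol();
  NumericMatrix tmp(ny, nx), out(ny, nx);
  std::vector<double> line, res;
  line.reserve(std::max(ny, nx));
  for (int y = 0; y < ny; ++y) {
    line.assign(nx, 0.0); res.assign(nx, 0.0);
    for (int x = 0; x < nx; ++x) line[x] = img(y, x);
    runmm1d(line, res, nx, r, erode);
    for (int x = 0; x < nx; ++x) tmp(y, x) = res[x];
  }
  for (int x = 0; x < nx; ++x) {
    line.assign(ny, 0.0); res.assign(ny, 0.0);
    for (int y = 0; y < ny; ++y) line[y] = tmp(y, x);
    runmm1d(line, res, ny, r, erode);
    for (int y = 0; y < ny; ++y) out(y, x) = res[y];
  }
  return out;
}

// 8-connected component labeling of a binary matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_label2d(LogicalMatrix bw) {
  int ny = bw.nrow(), nx = bw.ncol();
  IntegerMatrix lab(ny, nx);
  int next = 0;
  std::vector<std::pair<int, int>> stack;
  for (int x0 = 0; x0 < nx; ++x0)
    for (int y0 = 0; y0 < ny; ++y0) {
      if (!bw(y0, x0) || lab(y0, x0) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back({y0, x0});
      lab(y0, x0) = next;
      while (!stack.empty()) {
        auto [y, x] = stack.back();
        stack.pop_back();
        for (int dx = -1; dx <= 1; ++dx)
          for (int dy = -1; dy <= 1; ++dy) {
            int yy = y + dy, xx = x + dx;
            if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
            if (bw(yy, xx) && lab(yy, xx) == 0) {
              lab(yy, xx) = next;
              stack.push_back({yy, xx});
            }
          }
      }
    }
  return lab;
}

// Zhang-Suen thinning of a binary matrix to a 1-px skeleton.
// [[Rcpp::export]]
LogicalMatrix cpp_thin2d(LogicalMatrix bw) {
  int ny = bw.nrow(), nx = bw.ncol();
  std::vector<char> img((size_t)ny * nx);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) img[y + (size_t)ny * x] = bw(y, x) ? 1 : 0;
  auto at = [&](int y, int x) -> char {
    if (y < 0 || y >= ny || x < 0 || x >= nx) return 0;
    return img[y + (size_t)ny * x];
  };
  bool changed = true;
  std::vector<std::pair<int, int>> kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int x = 0; x < nx; ++x)
        for (int y = 0; y < ny; ++y) {
          if (!at(y, x)) continue;
          // neighbours P2..P9 clockwise from north
          char p2 = at(y - 1, x), p3 = at(y - 1, x + 1), p4 = at(y, x + 1),
               p5 = at(y + 1, x + 1), p6 = at(y + 1, x), p7 = at(y + 1, x - 1),
               p8 = at(y, x - 1), p9 = at(y - 1, x - 1);
          int bn = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (bn < 2 || bn > 6) continue;
          char seq[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
          int an = 0;
          for (int i = 0; i < 8; ++i)
            if (!seq[i] && seq[i + 1]) ++an;
          if (an != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0) continue;
            if (p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0) continue;
            if (p2 * p6 * p8 != 0) continue;
          }
          kill.push_back({y, x});
        }
      if (!kill.empty()) changed = true;
      for (auto& yx : kill) img[yx.first + (size_t)ny * yx.second] = 0;
    }
  }
  LogicalMatrix out(ny, nx);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) out(y, x) = img[y + (size_t)ny * x] != 0;
  return out;
}

// Count of 8-connected skeleton neighbours for every pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_count2d(LogicalMatrix bw) {
  int ny = bw.nrow(), nx = bw.ncol();
  IntegerMatrix out(ny, nx);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      if (!bw(y, x)) { out(y, x) = NA_INTEGER; continue; }
      int c = 0;
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy) {
          if (dx == 0 && dy == 0) continue;
          int yy = y + dy, xx = x + dx;
          if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
          if (bw(yy, xx)) ++c;
        }
      out(y, x) = c;
    }
  return out;
}
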
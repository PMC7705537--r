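#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <deque>
#include <unordered_map>
#include <algorithm>
#include <limits>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// separable Gaussian-derivative convolution (reflection boundary)
// ---------------------------------------------------------------------------

static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  return (i < n) ? i : period - i - 1;
}

// correlate along rows (the y direction): dst(r,c) = sum_j k[j] src(r+j-r0, c)
static void corr_y(const NumericMatrix& src, NumericMatrix& dst,
                   const std::vector<double>& k) {
  int nr = src.nrow(), nc = src.ncol(), r0 = ((int)k.size() - 1) / 2;
  for (int c = 0; c < nc; ++c) {
    const double* sc = &src(0, c);
    double* dc = &dst(0, c);
    int lo = std::min(r0, nr), hi = std::max(lo, nr - r0);
    for (int r = 0; r < lo; ++r) {
      double s = 0.0;
      for (int j = -r0; j <= r0; ++j) s += k[j + r0] * sc[reflect_idx(r + j, nr)];
      dc[r] = s;
    }
    for (int r = lo; r < hi; ++r) {
      double s = 0.0;
      const double* p = sc + r - r0;
      for (int j = 0; j < 2 * r0 + 1; ++j) s += k[j] * p[j];
      dc[r] = s;
    }
    for (int r = hi; r < nr; ++r) {
      double s = 0.0;
      for (int j = -r0; j <= r0; ++j) s += k[j + r0] * sc[reflect_idx(r + j, nr)];
      dc[r] = s;
    }
  }
}

// correlate along columns (the x direction); column-wise AXPY accumulation
static void corr_x(const NumericMatrix& src, NumericMatrix& dst,
                   const std::vector<double>& k) {
  int nr = src.nrow(), nc = src.ncol(), r0 = ((int)k.size() - 1) / 2;
  std::fill(dst.begin(), dst.end(), 0.0);
  for (int c = 0; c < nc; ++c) {
    double* dc = &dst(0, c);
    for (int j = -r0; j <= r0; ++j) {
      double kj = k[j + r0];
      const double* sc = &src(0, reflect_idx(c + j, nc));
      for (int r = 0; r < nr; ++r) dc[r] += kj * sc[r];
    }
  }
}

// Discrete kernels normalized so that responses to constant / ramp /
// half-square inputs are exact (0th, 1st, 2nd derivative respectively).
static void gauss_kernels(double sigma, std::vector<double>& g,
                          std::vector<double>& dg, std::vector<double>& ddg) {
  int r = (int)std::ceil(3.5 * sigma);
  int len = 2 * r + 1;
  g.assign(len, 0.0); dg.assign(len, 0.0); ddg.assign(len, 0.0);
  double sg = 0.0;
  for (int j = -r; j <= r; ++j) {
    g[j + r] = std::exp(-0.5 * j * j / (sigma * sigma));
    sg += g[j + r];
  }
  for (int j = 0; j < len; ++j) g[j] /= sg;
  double s1 = 0.0;
  for (int j = -r; j <= r; ++j) { dg[j + r] = j * g[j + r]; s1 += j * dg[j + r]; }
  for (int j = 0; j < len; ++j) dg[j] /= s1;
  // second-derivative kernel: zero response to constants (via the discrete
  // variance v), unit response to x^2/2
  double v = 0.0;
  for (int j = -r; j <= r; ++j) v += (double)j * j * g[j + r];
  for (int j = -r; j <= r; ++j) ddg[j + r] = ((double)j * j - v) * g[j + r];
  double s2 = 0.0;
  for (int j = -r; j <= r; ++j) s2 += 0.5 * j * j * ddg[j + r];
  for (int j = 0; j < len; ++j) ddg[j] /= s2;
}

// [[Rcpp::export]]
List cpp_gaussian_derivatives(NumericMatrix img, double sigma) {
  std::vector<double> g, dg, ddg;
  gauss_kernels(sigma, g, dg, ddg);
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix sg(nr, nc), sdg(nr, nc), sddg(nr, nc);
  corr_y(img, sg, g);
  corr_y(img, sdg, dg);
  corr_y(img, sddg, ddg);
  NumericMatrix rx(nr, nc), ry(nr, nc), rxx(nr, nc), rxy(nr, nc), ryy(nr, nc);
  corr_x(sg, rx, dg);    // d/dx
  corr_x(sdg, ry, g);    // d/dy
  corr_x(sg, rxx, ddg);  // d2/dx2
  corr_x(sdg, rxy, dg);  // d2/dxdy
  corr_x(sddg, ryy, g);  // d2/dy2
  return List::create(_["rx"] = rx, _["ry"] = ry, _["rxx"] = rxx,
                      _["rxy"] = rxy, _["ryy"] = ryy);
}

// ---------------------------------------------------------------------------
// Hessian ridge point extraction (bright ridges)
// ---------------------------------------------------------------------------

// Returns matrix with columns x, y, direction, strength, row, col.
// Coordinates are 1-based pixel centers; x runs along columns, y along rows.
// [[Rcpp::export]]
NumericMatrix cpp_ridge_points(NumericMatrix rx, NumericMatrix ry,
                               NumericMatrix rxx, NumericMatrix rxy,
                               NumericMatrix ryy, double min_strength) {
  int nr = rx.nrow(), nc = rx.ncol();
  std::vector<double> out;
  out.reserve(6 * 4096);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double a = rxx(r, c), bq = rxy(r, c), d = ryy(r, c);
      double tr = a + d;
      double disc = std::sqrt((a - d) * (a - d) + 4.0 * bq * bq);
      double lmin = 0.5 * (tr - disc);
      if (lmin >= -1e-300) continue;          // not a bright ridge
      double strength = -lmin;
      if (strength < min_strength) continue;
      // eigenvector of lmin (= ridge normal)
      double vx, vy;
      double e1x = bq, e1y = lmin - a;
      double e2x = lmin - d, e2y = bq;
      if (e1x * e1x + e1y * e1y >= e2x * e2x + e2y * e2y) { vx = e1x; vy = e1y; }
      else { vx = e2x; vy = e2y; }
      double nv = std::sqrt(vx * vx + vy * vy);
      if (nv < 1e-300) continue;
      vx /= nv; vy /= nv;
      // zero of the first directional derivative of the 2nd-order model
      double t = -(rx(r, c) * vx + ry(r, c) * vy) / lmin;
      if (std::fabs(t) > 0.5) continue;       // must fall inside the pixel
      double px = (c + 1) + t * vx;
      double py = (r + 1) + t * vy;
      double ang = std::atan2(vx, -vy);       // tangent = normal rotated 90 deg
      if (ang < 0) ang += M_PI;
      if (ang >= M_PI) ang -= M_PI;
      out.push_back(px); out.push_back(py); out.push_back(ang);
      out.push_back(strength); out.push_back(r + 1); out.push_back(c + 1);
    }
  }
  int n = (int)out.size() / 6;
  NumericMatrix res(n, 6);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 6; ++j) res(i, j) = out[6 * i + j];
  colnames(res) = CharacterVector::create("x", "y", "direction", "strength",
                                          "row", "col");
  return res;
}

// strength field (-lambda_min clamped at 0) used for threshold calibration
// [[Rcpp::export]]
NumericMatrix cpp_ridge_strength(NumericMatrix rxx, NumericMatrix rxy,
                                 NumericMatrix ryy) {
  int nr = rxx.nrow(), nc = rxx.ncol();
  NumericMatrix s(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double a = rxx(r, c), bq = rxy(r, c), d = ryy(r, c);
      double lmin = 0.5 * ((a + d) -
                    std::sqrt((a - d) * (a - d) + 4.0 * bq * bq));
      s(r, c) = lmin < 0 ? -lmin : 0.0;
    }
  return s;
}

// ---------------------------------------------------------------------------
// DBSCAN on 2-D points (grid-accelerated, deterministic by index order)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_dbscan(NumericVector x, NumericVector y, double eps,
                         int min_pts) {
  int n = x.size();
  IntegerVector labels(n, 0);                 // 0 = noise
  if (n == 0) return labels;
  double eps2 = eps * eps;
  double x0 = *std::min_element(x.begin(), x.end());
  double y0 = *std::min_element(y.begin(), y.end());
  std::unordered_map<long long, std::vector<int> > grid;
  auto key = [&](double xv, double yv) {
    long long gx = (long long)std::floor((xv - x0) / eps);
    long long gy = (long long)std::floor((yv - y0) / eps);
    return gx * 2000003LL + gy;
  };
  for (int i = 0; i < n; ++i) grid[key(x[i], y[i])].push_back(i);
  auto neighbors = [&](int i, std::vector<int>& nb) {
    nb.clear();
    long long gx = (long long)std::floor((x[i] - x0) / eps);
    long long gy = (long long)std::floor((y[i] - y0) / eps);
    for (long long dx = -1; dx <= 1; ++dx)
      for (long long dy = -1; dy <= 1; ++dy) {
        auto it = grid.find((gx + dx) * 2000003LL + (gy + dy));
        if (it == grid.end()) continue;
        for (int j : it->second) {
          double ddx = x[j] - x[i], ddy = y[j] - y[i];
          if (ddx * ddx + ddy * ddy <= eps2) nb.push_back(j);
        }
      }
    std::sort(nb.begin(), nb.end());
  };
  std::vector<char> visited(n, 0);
  std::vector<int> nb, nb2;
  int cl = 0;
  for (int i = 0; i < n; ++i) {
    if (visited[i]) continue;
    visited[i] = 1;
    neighbors(i, nb);
    if ((int)nb.size() < min_pts) continue;   // not a core point (counts self)
    ++cl;
    labels[i] = cl;
    std::deque<int> seedq(nb.begin(), nb.end());
    while (!seedq.empty()) {
      int j = seedq.front(); seedq.pop_front();
      if (labels[j] == 0) labels[j] = cl;     // noise or unclaimed -> border
      if (visited[j]) continue;
      visited[j] = 1;
      labels[j] = cl;
      neighbors(j, nb2);
      if ((int)nb2.size() >= min_pts)
        for (int q : nb2) if (!visited[q] || labels[q] == 0) seedq.push_back(q);
    }
  }
  return labels;
}

// ---------------------------------------------------------------------------
// mutual-neighbor linking along local tangent directions
// ---------------------------------------------------------------------------

struct DSU {
  std::vector<int> p;
  DSU(int n) : p(n) { for (int i = 0; i < n; ++i) p[i] = i; }
  int find(int a) { while (p[a] != a) { p[a] = p[p[a]]; a = p[a]; } return a; }
  void unite(int a, int b) { a = find(a); b = find(b); if (a != b) p[std::max(a,b)] = std::min(a,b); }
};

// Each point proposes <=1 neighbor forward and <=1 backward along its tangent,
// searching the Chebyshev shells of radius 1 and 2 around its pixel, within an
// angular tolerance. An edge exists only under mutual proposal.
// [[Rcpp::export]]
List cpp_steger_links(NumericVector x, NumericVector y, IntegerVector prow,
                      IntegerVector pcol, NumericVector dir, int nr, int nc,
                      double angle_tol_rad) {
  int n = x.size();
  IntegerMatrix prop(n, 2);
  std::fill(prop.begin(), prop.end(), NA_INTEGER);
  IntegerVector labels(n, NA_INTEGER);
  if (n == 0)
    return List::create(_["labels"] = labels,
                        _["edges"] = IntegerMatrix(0, 2));
  std::vector<int> pix((size_t)nr * nc, -1);
  for (int i = 0; i < n; ++i) {
    if (prow[i] < 1 || prow[i] > nr || pcol[i] < 1 || pcol[i] > nc)
      stop("centerline point pixel outside the stated image dimensions");
    pix[(size_t)(pcol[i] - 1) * nr + (prow[i] - 1)] = i;
  }
  double ctol = std::cos(angle_tol_rad);
  for (int i = 0; i < n; ++i) {
    double tx = std::cos(dir[i]), ty = std::sin(dir[i]);
    for (int s = 0; s < 2; ++s) {
      double sgn = s == 0 ? 1.0 : -1.0;
      int best = -1; double bestd = std::numeric_limits<double>::infinity();
      for (int dr = -2; dr <= 2; ++dr) {
        for (int dc = -2; dc <= 2; ++dc) {
          if (dr == 0 && dc == 0) continue;
          int rr = prow[i] - 1 + dr, cc = pcol[i] - 1 + dc;
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          int j = pix[(size_t)cc * nr + rr];
          if (j < 0) continue;
          double dx = x[j] - x[i], dy = y[j] - y[i];
          double proj = sgn * (dx * tx + dy * ty);
          if (proj <= 0) continue;
          double dd = std::sqrt(dx * dx + dy * dy);
          if (dd < 1e-12) continue;
          if (proj / dd < ctol) continue;
          if (dd < bestd - 1e-12 || (std::fabs(dd - bestd) <= 1e-12 && j < best)) {
            bestd = dd; best = j;
          }
        }
      }
      if (best >= 0) prop(i, s) = best + 1;   // 1-based
    }
  }
  // mutual edges + union-find
  DSU dsu(n);
  std::vector<int> ea, eb;
  auto proposes = [&](int a, int b) {
    return (prop(a, 0) != NA_INTEGER && prop(a, 0) == b + 1) ||
           (prop(a, 1) != NA_INTEGER && prop(a, 1) == b + 1);
  };
  for (int i = 0; i < n; ++i)
    for (int s = 0; s < 2; ++s) {
      if (prop(i, s) == NA_INTEGER) continue;
      int j = prop(i, s) - 1;
      if (j > i && proposes(j, i)) { dsu.unite(i, j); ea.push_back(i + 1); eb.push_back(j + 1); }
      if (j < i && proposes(j, i)) { dsu.unite(i, j); }
    }
  // compact component labels in order of first appearance
  std::unordered_map<int, int> remap;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = dsu.find(i);
    auto it = remap.find(r);
    if (it == remap.end()) { remap[r] = ++next; labels[i] = next; }
    else labels[i] = it->second;
  }
  IntegerMatrix edges((int)ea.size(), 2);
  for (size_t k = 0; k < ea.size(); ++k) { edges(k, 0) = ea[k]; edges(k, 1) = eb[k]; }
  return List::create(_["labels"] = labels, _["edges"] = edges);
}

// ---------------------------------------------------------------------------
// analytic Gaussian-profile ridge renderer (multiplicative attenuation)
// ---------------------------------------------------------------------------

// canvas is modified in place: canvas *= (1 - contrast*exp(-d^2/(2 sd^2)))
// where d is the distance to the densely sampled centerline polyline.
// [[Rcpp::export]]
void cpp_render_ridge(NumericMatrix canvas, NumericMatrix pts, double sd,
                      double contrast) {
  int nr = canvas.nrow(), nc = canvas.ncol();
  int np = pts.nrow();
  if (np == 0) return;
  int R = (int)std::ceil(3.5 * sd) + 1;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> d2((size_t)nr * nc, INF);
  std::vector<size_t> touched;
  touched.reserve(4096);
  for (int k = 0; k < np; ++k) {
    double px = pts(k, 0), py = pts(k, 1);   // x = col coord, y = row coord
    int c0 = std::max(0, (int)std::floor(px - 1 - R));
    int c1 = std::min(nc - 1, (int)std::ceil(px - 1 + R));
    int r0 = std::max(0, (int)std::floor(py - 1 - R));
    int r1 = std::min(nr - 1, (int)std::ceil(py - 1 + R));
    for (int c = c0; c <= c1; ++c) {
      double dx = (c + 1) - px;
      for (int r = r0; r <= r1; ++r) {
        double dy = (r + 1) - py;
        double dd = dx * dx + dy * dy;
        size_t idx = (size_t)c * nr + r;
        if (d2[idx] == INF) touched.push_back(idx);
        if (dd < d2[idx]) d2[idx] = dd;
      }
    }
  }
  double inv = 1.0 / (2.0 * sd * sd);
  for (size_t idx : touched)
    canvas[idx] *= (1.0 - contrast * std::exp(-d2[idx] * inv));
}
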
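// Nearest-neighbour point-set distances and connected-component labelling.

#include <Rcpp.h>
#include <cmath>
#include <queue>

// Rotate a matrix about the image centre by inverse mapping. bilinear = true
// uses bilinear interpolation (images); false uses nearest-neighbour with
// round-half-to-even, matching R's round() (label masks). Out-of-source
// pixels take `fill`.
// [[Rcpp::export(name = ".rot_resample")]]
Rcpp::NumericMatrix rot_resample(Rcpp::NumericMatrix m, double angle_deg,
                                 double fill, bool bilinear) {
  const int H = m.nrow(), W = m.ncol();
  Rcpp::NumericMatrix out(H, W);
  const double cc = (W + 1) / 2.0, rc = (H + 1) / 2.0;
  const double th = -angle_deg * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  for (int j = 0; j < W; ++j) {
    const double dx = (j + 1) - cc;
    for (int i = 0; i < H; ++i) {
      const double dy = (i + 1) - rc;
      const double sx = cc + ct * dx - st * dy;
      const double sy = rc + st * dx + ct * dy;
      double v = fill;
      if (bilinear) {
        const double x0 = std::floor(sx), y0 = std::floor(sy);
        if (x0 >= 1 && x0 + 1 <= W && y0 >= 1 && y0 + 1 <= H) {
          const double fx = sx - x0, fy = sy - y0;
          const int c0 = (int)x0 - 1, r0 = (int)y0 - 1;
          v = (1 - fy) * ((1 - fx) * m(r0, c0) + fx * m(r0, c0 + 1)) +
              fy * ((1 - fx) * m(r0 + 1, c0) + fx * m(r0 + 1, c0 + 1));
        }
      } else {
        const double xr = std::nearbyint(sx), yr = std::nearbyint(sy);
        if (xr >= 1 && xr <= W && yr >= 1 && yr <= H)
          v = m((int)yr - 1, (int)xr - 1);
      }
      out(i, j) = v;
    }
  }
  return out;
}

// For each row of A (points, columns = coordinates), the minimum Euclidean
// distance to any row of B, with per-axis physical spacing.
// [[Rcpp::export(name = ".nn_min_dist")]]
Rcpp::NumericVector nn_min_dist(Rcpp::NumericMatrix A, Rcpp::NumericMatrix B,
                                Rcpp::NumericVector spacing) {
  const int na = A.nrow(), nb = B.nrow(), d = A.ncol();
  if (B.ncol() != d) Rcpp::stop("dimension mismatch between point sets");
  if (spacing.size() != d) Rcpp::stop("spacing length must match columns");
  if (nb == 0) Rcpp::stop("second point set is empty");
  Rcpp::NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        const double v = (A(i, k) - B(j, k)) * spacing[k];
        s += v * v;
      }
      if (s < best) best = s;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Label foreground of a 3D logical/integer array. connectivity: 6 or 26
// (a 2D image passed as nz = 1 gives 4- or 8-connectivity). Returns integer
// labels (0 = background), numbered in order of first (smallest linear
// index) encounter, so ties between component sizes can be broken
// deterministically by label order.
// [[Rcpp::export(name = ".label_cc")]]
Rcpp::IntegerVector label_cc(Rcpp::IntegerVector mask, int nx, int ny, int nz,
                             int connectivity) {
  if ((R_xlen_t)nx * ny * nz != mask.size())
    Rcpp::stop("dimensions do not match mask length");
  if (connectivity != 6 && connectivity != 26)
    Rcpp::stop("connectivity must be 6 or 26");
  Rcpp::IntegerVector lab(mask.size(), 0);
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        const int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offs.push_back({dx, dy, dz});
      }
  auto at = [&](int x, int y, int z) -> R_xlen_t {
    return (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
  };
  int next = 0;
  std::queue<std::array<int, 3>> q;
  for (R_xlen_t p = 0; p < mask.size(); ++p) {
    if (!mask[p] || lab[p]) continue;
    ++next;
    const int z0 = (int)(p / ((R_xlen_t)nx * ny));
    const int rem = (int)(p % ((R_xlen_t)nx * ny));
    q.push({rem % nx, rem / nx, z0});
    lab[p] = next;
    while (!q.empty()) {
      auto c = q.front();
      q.pop();
      for (auto& o : offs) {
        const int x = c[0] + o[0], y = c[1] + o[1], z = c[2] + o[2];
        if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
        const R_xlen_t pp = at(x, y, z);
        if (mask[pp] && !lab[pp]) {
          lab[pp] = next;
          q.push({x, y, z});
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}
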
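#include <Rcpp.h>
#include <queue>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Volumes are R arrays with dim = (nz, ny, nx), column-major:
// linear index = z + nz * (y + ny * x), all 0-based here.

static inline int reflect(int i, int n) {
  // reflect-101-style border without repeating the edge twice would be
  // (2n - 2 - i); plain reflection (edge repeated) matches the documented
  // border policy: ... 2 1 0 | 0 1 2 ... n-1 | n-1 n-2 ...
  // iterate so offsets larger than the axis length fold repeatedly
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export]]
NumericVector cpp_median3d(NumericVector vol, IntegerVector dim, int k) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int r = k / 2;
  NumericVector out(vol.size());
  std::vector<double> buf;
  buf.reserve((size_t)k * k * k);
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        buf.clear();
        for (int dx = -r; dx <= r; ++dx) {
          int xx = reflect(x + dx, nx);
          for (int dy = -r; dy <= r; ++dy) {
            int yy = reflect(y + dy, ny);
            for (int dz = -r; dz <= r; ++dz) {
              int zz = reflect(z + dz, nz);
              buf.push_back(vol[zz + nz * (yy + (R_xlen_t)ny * xx)]);
            }
          }
        }
        size_t m = buf.size() / 2;
        std::nth_element(buf.begin(), buf.begin() + m, buf.end());
        double med = buf[m];
        if (buf.size() % 2 == 0) {
          std::nth_element(buf.begin(), buf.begin() + m - 1, buf.begin() + m);
          med = 0.5 * (med + buf[m - 1]);
        }
        out[z + nz * (y + (R_xlen_t)ny * x)] = med;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Separable 1-D convolution along one axis (0 = z, 1 = y, 2 = x),
// reflected borders; kernel length must be odd.
// [[Rcpp::export]]
NumericVector cpp_conv_axis(NumericVector vol, IntegerVector dim,
                            NumericVector kernel, int axis) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int kl = kernel.size(), r = kl / 2;
  NumericVector out(vol.size());
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        double acc = 0.0;
        for (int t = -r; t <= r; ++t) {
          int zz = z, yy = y, xx = x;
          if (axis == 0) zz = reflect(z + t, nz);
          else if (axis == 1) yy = reflect(y + t, ny);
          else xx = reflect(x + t, nx);
          acc += kernel[t + r] * vol[zz + nz * (yy + (R_xlen_t)ny * xx)];
        }
        out[z + nz * (y + (R_xlen_t)ny * x)] = acc;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Local maxima within a Chebyshev box of per-axis radius (rz, ry, rx),
// value strictly above `thresh`. Plateaus resolved by lowest linear index.
// Returns 1-based linear indices.
// [[Rcpp::export]]
IntegerVector cpp_local_max(NumericVector vol, IntegerVector dim,
                            int rz, int ry, int rx, double thresh) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<int> hits;
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = z + nz * (y + (R_xlen_t)ny * x);
        double v = vol[i];
        if (!(v > thresh)) continue;
        bool ok = true;
        for (int dx = -rx; dx <= rx && ok; ++dx) {
          int xx = x + dx; if (xx < 0 || xx >= nx) continue;
          for (int dy = -ry; dy <= ry && ok; ++dy) {
            int yy = y + dy; if (yy < 0 || yy >= ny) continue;
            for (int dz = -rz; dz <= rz && ok; ++dz) {
              int zz = z + dz; if (zz < 0 || zz >= nz) continue;
              R_xlen_t j = zz + nz * (yy + (R_xlen_t)ny * xx);
              if (j == i) continue;
              if (vol[j] > v || (vol[j] == v && j < i)) ok = false;
            }
          }
        }
        if (ok) hits.push_back((int)i + 1);
      }
    }
  }
  return wrap(hits);
}

// Integer-shift normalised cross-correlation registration.
// Finds s = (dz,dy,dx), |s| <= maxShift, maximising the Pearson
// correlation of ref[p] with mov[p + s] over the overlap region.
// [[Rcpp::export]]
List cpp_register_ncc(NumericVector ref, NumericVector mov,
                      IntegerVector dim, IntegerVector maxShift) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int mz = maxShift[0], my = maxShift[1], mx = maxShift[2];
  double best = -2.0;
  int bz = 0, by = 0, bx = 0;
  for (int sx = -mx; sx <= mx; ++sx) {
    int x0 = std::max(0, -sx), x1 = std::min(nx, nx - sx);
    for (int sy = -my; sy <= my; ++sy) {
      int y0 = std::max(0, -sy), y1 = std::min(ny, ny - sy);
      for (int sz = -mz; sz <= mz; ++sz) {
        int z0 = std::max(0, -sz), z1 = std::min(nz, nz - sz);
        double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
        R_xlen_t n = 0;
        for (int x = x0; x < x1; ++x) {
          for (int y = y0; y < y1; ++y) {
            R_xlen_t ia = z0 + nz * (y + (R_xlen_t)ny * x);
            R_xlen_t ib = (z0 + sz) + nz * ((y + sy) + (R_xlen_t)ny * (x + sx));
            for (int z = z0; z < z1; ++z, ++ia, ++ib) {
              double a = ref[ia], b = mov[ib];
              sa += a; sb += b; saa += a * a; sbb += b * b; sab += a * b;
              ++n;
            }
          }
        }
        if (n < 2) continue;
        double va = saa - sa * sa / n, vb = sbb - sb * sb / n;
        if (va <= 0 || vb <= 0) continue;
        double r = (sab - sa * sb / n) / std::sqrt(va * vb);
        // deterministic tie-break: smaller shift magnitude, then lexicographic
        if (r > best + 1e-12 ||
            (std::abs(r - best) <= 1e-12 &&
             (std::abs(sz) + std::abs(sy) + std::abs(sx) <
              std::abs(bz) + std::abs(by) + std::abs(bx)))) {
          best = r; bz = sz; by = sy; bx = sx;
        }
      }
    }
  }
  return List::create(_["shift"] = IntegerVector::create(bz, by, bx),
                      _["score"] = best);
}

struct WsNode {
  double elev;
  long long order;
  R_xlen_t idx;
};
struct WsCmp {
  bool operator()(const WsNode &a, const WsNode &b) const {
    if (a.elev != b.elev) return a.elev > b.elev;   // lower elevation first
    return a.order > b.order;                       // FIFO among ties
  }
};

// Seeded watershed by ordered flooding on the elevation map, 6-connectivity.
// seeds: integer volume, 0 = unlabelled; mask: logical foreground.
// [[Rcpp::export]]
IntegerVector cpp_seeded_watershed(NumericVector elev, IntegerVector dim,
                                   IntegerVector seeds, LogicalVector mask) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  IntegerVector lab(clone(seeds));
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long long counter = 0;
  const int dzs[6] = {1, -1, 0, 0, 0, 0};
  const int dys[6] = {0, 0, 1, -1, 0, 0};
  const int dxs[6] = {0, 0, 0, 0, 1, -1};
  for (R_xlen_t i = 0; i < lab.size(); ++i)
    if (lab[i] > 0 && mask[i]) pq.push({elev[i], counter++, i});
  while (!pq.empty()) {
    WsNode nd = pq.top(); pq.pop();
    R_xlen_t i = nd.idx;
    int z = (int)(i % nz), y = (int)((i / nz) % ny), x = (int)(i / ((R_xlen_t)nz * ny));
    for (int d = 0; d < 6; ++d) {
      int zz = z + dzs[d], yy = y + dys[d], xx = x + dxs[d];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      R_xlen_t j = zz + nz * (yy + (R_xlen_t)ny * xx);
      if (!mask[j] || lab[j] != 0) continue;
      lab[j] = lab[i];
      pq.push({std::max(elev[j], nd.elev), counter++, j});
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Connected components of the nonzero voxels of an integer volume; a
// component never crosses voxels holding different input values. conn is
// 6 or 26. Returns a component labelling 1..K (0 = background).
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector vol, IntegerVector dim,
                                   int conn) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  IntegerVector out(vol.size());
  std::vector<std::array<int, 3>> offs;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        if (conn == 6 && std::abs(dz) + std::abs(dy) + std::abs(dx) != 1) continue;
        offs.push_back({dz, dy, dx});
      }
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < vol.size(); ++s) {
    if (vol[s] == 0 || out[s] != 0) continue;
    int val = vol[s];
    out[s] = ++next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t i = stack.back(); stack.pop_back();
      int z = (int)(i % nz), y = (int)((i / nz) % ny), x = (int)(i / ((R_xlen_t)nz * ny));
      for (auto &o : offs) {
        int zz = z + o[0], yy = y + o[1], xx = x + o[2];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        R_xlen_t j = zz + nz * (yy + (R_xlen_t)ny * xx);
        if (vol[j] == val && out[j] == 0) {
          out[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Add a dense Gaussian blob patch to a volume in place around centre
// (cz, cy, cx) (0-based, fractional allowed) with per-axis sigma in voxels
// and peak amplitude amp; patch extends to `ext` sigmas.
// [[Rcpp::export]]
void cpp_add_blob(NumericVector vol, IntegerVector dim,
                  double cz, double cy, double cx,
                  double sz, double sy, double sx,
                  double amp, double ext) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  int z0 = std::max(0, (int)std::floor(cz - ext * sz));
  int z1 = std::min(nz - 1, (int)std::ceil(cz + ext * sz));
  int y0 = std::max(0, (int)std::floor(cy - ext * sy));
  int y1 = std::min(ny - 1, (int)std::ceil(cy + ext * sy));
  int x0 = std::max(0, (int)std::floor(cx - ext * sx));
  int x1 = std::min(nx - 1, (int)std::ceil(cx + ext * sx));
  for (int x = x0; x <= x1; ++x) {
    double qx = (x - cx) / sx;
    for (int y = y0; y <= y1; ++y) {
      double qy = (y - cy) / sy;
      for (int z = z0; z <= z1; ++z) {
        double qz = (z - cz) / sz;
        vol[z + nz * (y + (R_xlen_t)ny * x)] +=
          amp * std::exp(-0.5 * (qz * qz + qy * qy + qx * qx));
      }
    }
  }
}

// Nearest-centroid (anisotropic Voronoi) labelling of masked voxels.
// cents: K x 3 matrix of (z, y, x) centroids in voxel units (0-based);
// scale: per-axis metric weights (voxel size in um).
// [[Rcpp::export]]
IntegerVector cpp_voronoi_labels(IntegerVector dim, NumericMatrix cents,
                                 NumericVector scale, LogicalVector mask) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int K = cents.nrow();
  IntegerVector out((R_xlen_t)nz * ny * nx);
  const double wz = scale[0], wy = scale[1], wx = scale[2];
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = z + nz * (y + (R_xlen_t)ny * x);
        if (!mask[i]) { out[i] = 0; continue; }
        double bd = R_PosInf; int bk = 0;
        for (int k = 0; k < K; ++k) {
          double dz = (z - cents(k, 0)) * wz;
          double dy = (y - cents(k, 1)) * wy;
          double dx = (x - cents(k, 2)) * wx;
          double d = dz * dz + dy * dy + dx * dx;
          if (d < bd) { bd = d; bk = k + 1; }
        }
        out[i] = bk;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}
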
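#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Per-slice median over a circular (disc) neighbourhood of the given radius,
// bounding box (2r+1)^2, with mirror boundary handling. `slice` is ny x nx.
// [[Rcpp::export(name = ".median_disc_2d")]]
NumericMatrix median_disc_2d(NumericMatrix slice, int radius) {
  const int ny = slice.nrow(), nx = slice.ncol();
  std::vector<int> offy, offx;
  for (int dy = -radius; dy <= radius; ++dy)
    for (int dx = -radius; dx <= radius; ++dx)
      if (dy * dy + dx * dx <= radius * radius) {
        offy.push_back(dy);
        offx.push_back(dx);
      }
  const int m = (int)offy.size();
  NumericMatrix out(ny, nx);
  std::vector<double> buf(m);
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int k = 0; k < m; ++k) {
        int yy = y + offy[k];
        int xx = x + offx[k];
        if (yy < 0) yy = -yy;               // mirror about the edge sample
        if (yy >= ny) yy = 2 * ny - 2 - yy;
        if (xx < 0) xx = -xx;
        if (xx >= nx) xx = 2 * nx - 2 - xx;
        buf[k] = slice(yy, xx);
      }
      std::nth_element(buf.begin(), buf.begin() + m / 2, buf.end());
      double med = buf[m / 2];
      if (m % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + m / 2 - 1, buf.end());
        med = 0.5 * (med + buf[m / 2 - 1]);
      }
      out(y, x) = med;
    }
  }
  return out;
}

// Grayscale erosion/dilation of a 2D slice with a non-flat ball (spherical
// cap) structuring element of the given radius (voxels). The element height
// is h(d) = sqrt(R^2 - d^2) - R <= 0 within |d| <= R. Pixels outside the
// image do not constrain the result (border handling by omission).
// [[Rcpp::export(name = ".ball_morph_2d")]]
NumericMatrix ball_morph_2d(NumericMatrix slice, double radius, bool erode) {
  const int ny = slice.nrow(), nx = slice.ncol();
  const int r = (int)std::floor(radius);
  NumericMatrix out(ny, nx);
  if (2 * r + 1 >= ny && 2 * r + 1 >= nx) {
    // window covers the whole slice: loop over slice pixels directly with a
    // lookup of the element height by integer squared distance
    const int maxd2 = (ny - 1) * (ny - 1) + (nx - 1) * (nx - 1);
    std::vector<double> lut((size_t)maxd2 + 1, R_NaReal);
    for (int d2 = 0; d2 <= maxd2; ++d2)
      if ((double)d2 <= radius * radius)
        lut[d2] = std::sqrt(radius * radius - (double)d2) - radius;
    const double* s = REAL(slice);
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) {
        double acc = erode ? R_PosInf : R_NegInf;
        for (int xx = 0; xx < nx; ++xx) {
          const int dx2 = (xx - x) * (xx - x);
          const double* col = s + (size_t)xx * ny;
          for (int yy = 0; yy < ny; ++yy) {
            const int d2 = dx2 + (yy - y) * (yy - y);
            if ((double)d2 > radius * radius) continue;
            const double v = erode ? col[yy] - lut[d2] : col[yy] + lut[d2];
            if (erode ? (v < acc) : (v > acc)) acc = v;
          }
        }
        out(y, x) = acc;
      }
    }
    return out;
  }
  std::vector<int> offy, offx;
  std::vector<double> h;
  for (int dy = -r; dy <= r; ++dy)
    for (int dx = -r; dx <= r; ++dx) {
      double d2 = (double)dy * dy + (double)dx * dx;
      if (d2 <= radius * radius) {
        offy.push_back(dy);
        offx.push_back(dx);
        h.push_back(std::sqrt(radius * radius - d2) - radius);
      }
    }
  const int m = (int)offy.size();
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      double acc = erode ? R_PosInf : R_NegInf;
      for (int k = 0; k < m; ++k) {
        const int yy = y + offy[k];
        const int xx = x + offx[k];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        const double v = erode ? slice(yy, xx) - h[k] : slice(yy, xx) + h[k];
        if (erode ? (v < acc) : (v > acc)) acc = v;
      }
      out(y, x) = acc;
    }
  }
  return out;
}

// ---- statistical region merging -------------------------------------------

static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// SRM on a 3D stack (vector `img`, dims nz x ny x nx, column-major z fastest
// as in R arrays). Values are expected in 0..g-1 (8-bit: g = 256).
// 6-connected neighbour pairs are processed in ascending order of absolute
// intensity difference; regions i, j merge when
//   (mean_i - mean_j)^2 <= b2(Ri) + b2(Rj),
//   b(R) = g * sqrt(log(2/delta) / (2 Q |R|)),  delta = 1/(6 N^2).
// Returns per-voxel region mean and the number of regions.
// [[Rcpp::export(name = ".srm_3d")]]
List srm_3d(NumericVector img, IntegerVector dims, double Q, double g) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t N = (R_xlen_t)nz * ny * nx;
  const double delta = 1.0 / (6.0 * (double)N * (double)N);
  const double logterm = std::log(2.0 / delta);

  // collect 6-connectivity edges, bucket-sorted by integer |difference|
  const int G = (int)g;
  std::vector<std::vector<std::pair<int, int> > > buckets(G + 1);
  auto idx = [&](int z, int y, int x) { return z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x); };
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = idx(z, y, x);
        if (z + 1 < nz) {
          int d = (int)std::lround(std::fabs(img[i] - img[idx(z + 1, y, x)]));
          buckets[std::min(d, G)].push_back(std::make_pair((int)i, (int)idx(z + 1, y, x)));
        }
        if (y + 1 < ny) {
          int d = (int)std::lround(std::fabs(img[i] - img[idx(z, y + 1, x)]));
          buckets[std::min(d, G)].push_back(std::make_pair((int)i, (int)idx(z, y + 1, x)));
        }
        if (x + 1 < nx) {
          int d = (int)std::lround(std::fabs(img[i] - img[idx(z, y, x + 1)]));
          buckets[std::min(d, G)].push_back(std::make_pair((int)i, (int)idx(z, y, x + 1)));
        }
      }

  std::vector<int> parent(N);
  std::vector<double> sum(N);
  std::vector<int> size(N, 1);
  for (R_xlen_t i = 0; i < N; ++i) {
    parent[i] = (int)i;
    sum[i] = img[i];
  }
  int nregions = (int)N;
  const double pref = g * g * logterm / (2.0 * Q);
  for (int b = 0; b <= G; ++b) {
    for (size_t e = 0; e < buckets[b].size(); ++e) {
      int ri = uf_find(parent, buckets[b][e].first);
      int rj = uf_find(parent, buckets[b][e].second);
      if (ri == rj) continue;
      const double mi = sum[ri] / size[ri];
      const double mj = sum[rj] / size[rj];
      const double diff = mi - mj;
      const double b2 = pref / size[ri] + pref / size[rj];
      if (diff * diff <= b2) {
        if (size[ri] < size[rj]) std::swap(ri, rj);
        parent[rj] = ri;
        sum[ri] += sum[rj];
        size[ri] += size[rj];
        --nregions;
      }
    }
  }
  NumericVector means((R_xlen_t)N);
  for (R_xlen_t i = 0; i < N; ++i) {
    int r = uf_find(parent, (int)i);
    means[i] = sum[r] / size[r];
  }
  return List::create(Named("means") = means, Named("n_regions") = nregions);
}
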
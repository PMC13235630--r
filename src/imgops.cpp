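// Volume primitives: separable Gaussian smoothing (zero-padded, for the PET
// point-spread-function model; replicate-padded 2D variant for SSIM windows)
// and trilinear grid resampling over a fixed physical extent.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static std::vector<double> gauss_kernel(double sigma, int radius) {
  std::vector<double> k(2 * radius + 1);
  double s = 0;
  for (int i = -radius; i <= radius; ++i) {
    k[i + radius] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + radius];
  }
  for (auto& v : k) v /= s;
  return k;
}

// [[Rcpp::export]]
arma::cube gaussian_blur3d_cpp(const arma::cube& v, const arma::vec& sigma) {
  arma::cube a = v, b(arma::size(v));
  const int nx = v.n_rows, ny = v.n_cols, nz = v.n_slices;
  const int dims[3] = {nx, ny, nz};
  for (int ax = 0; ax < 3; ++ax) {
    if (sigma[ax] <= 0) continue;
    const int r = std::max(1, (int)std::ceil(3.0 * sigma[ax]));
    std::vector<double> k = gauss_kernel(sigma[ax], r);
    b.zeros();
    const int n = dims[ax];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          const int c = ax == 0 ? x : (ax == 1 ? y : z);
          double acc = 0;
          for (int o = -r; o <= r; ++o) {
            const int cc = c + o;
            if (cc < 0 || cc >= n) continue;  // zero padding
            const double w = k[o + r];
            if (ax == 0) acc += w * a(cc, y, z);
            else if (ax == 1) acc += w * a(x, cc, z);
            else acc += w * a(x, y, cc);
          }
          b(x, y, z) = acc;
        }
    a = b;
  }
  return a;
}

// [[Rcpp::export]]
arma::mat gaussian_blur2d_replicate_cpp(const arma::mat& img, double sigma,
                                        int radius) {
  std::vector<double> k = gauss_kernel(sigma, radius);
  const int nr = img.n_rows, nc = img.n_cols;
  arma::mat t(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0;
      for (int o = -radius; o <= radius; ++o) {
        int ii = std::min(std::max(i + o, 0), nr - 1);
        acc += k[o + radius] * img(ii, j);
      }
      t(i, j) = acc;
    }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0;
      for (int o = -radius; o <= radius; ++o) {
        int jj = std::min(std::max(j + o, 0), nc - 1);
        acc += k[o + radius] * t(i, jj);
      }
      out(i, j) = acc;
    }
  return out;
}

// Target voxel centres are mapped into the source grid assuming both grids
// span the same physical extent; coordinates are edge-clamped.
// [[Rcpp::export]]
arma::cube resample_trilinear_cpp(const arma::cube& v, int nx, int ny, int nz) {
  arma::cube out(nx, ny, nz);
  const int sx = v.n_rows, sy = v.n_cols, sz = v.n_slices;
  auto src_coord = [](int i, int n_t, int n_s) {
    double c = (i + 0.5) * ((double)n_s / n_t) - 0.5;
    return std::min(std::max(c, 0.0), (double)n_s - 1.0);
  };
  for (int z = 0; z < nz; ++z) {
    const double cz = src_coord(z, nz, sz);
    const int z0 = (int)std::floor(cz), z1 = std::min(z0 + 1, sz - 1);
    const double fz = cz - z0;
    for (int y = 0; y < ny; ++y) {
      const double cy = src_coord(y, ny, sy);
      const int y0 = (int)std::floor(cy), y1 = std::min(y0 + 1, sy - 1);
      const double fy = cy - y0;
      for (int x = 0; x < nx; ++x) {
        const double cx = src_coord(x, nx, sx);
        const int x0 = (int)std::floor(cx), x1 = std::min(x0 + 1, sx - 1);
        const double fx = cx - x0;
        const double v00 = v(x0, y0, z0) * (1 - fx) + v(x1, y0, z0) * fx;
        const double v10 = v(x0, y1, z0) * (1 - fx) + v(x1, y1, z0) * fx;
        const double v01 = v(x0, y0, z1) * (1 - fx) + v(x1, y0, z1) * fx;
        const double v11 = v(x0, y1, z1) * (1 - fx) + v(x1, y1, z1) * fx;
        const double w0 = v00 * (1 - fy) + v10 * fy;
        const double w1 = v01 * (1 - fy) + v11 * fy;
        out(x, y, z) = w0 * (1 - fz) + w1 * fz;
      }
    }
  }
  return out;
}
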
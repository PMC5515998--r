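// Trilinear interpolation kernels for Fourier-slice projection,
// direct Fourier-inversion backprojection, real-space volume sampling
// and the local grid-search pose refiner. Conventions: all grids are
// "centered" (origin at voxel n/2, 0-based); coordinates passed in are
// offsets from that center in voxel / Fourier-pixel units.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline std::complex<double> tri_cx(const arma::cx_cube& F,
                                          double x, double y, double z) {
  const int n = F.n_rows;
  const double c = n / 2.0;
  const double gx = x + c, gy = y + c, gz = z + c;
  const int x0 = (int)std::floor(gx);
  const int y0 = (int)std::floor(gy);
  const int z0 = (int)std::floor(gz);
  if (x0 < 0 || y0 < 0 || z0 < 0 || x0 > n - 1 || y0 > n - 1 || z0 > n - 1)
    return std::complex<double>(0.0, 0.0);
  // clamp the upper neighbour at the grid edge (weight is 0 there when
  // the sample lies exactly on the last plane)
  const int x1 = x0 < n - 1 ? x0 + 1 : x0;
  const int y1 = y0 < n - 1 ? y0 + 1 : y0;
  const int z1 = z0 < n - 1 ? z0 + 1 : z0;
  const double fx = gx - x0, fy = gy - y0, fz = gz - z0;
  std::complex<double> v(0.0, 0.0);
  for (int dz = 0; dz < 2; ++dz)
    for (int dy = 0; dy < 2; ++dy)
      for (int dx = 0; dx < 2; ++dx) {
        const double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) * (dz ? fz : 1 - fz);
        v += w * F(dx ? x1 : x0, dy ? y1 : y0, dz ? z1 : z0);
      }
  return v;
}

// Extract the central slice normal to the rotated z axis from a centered
// 3D Fourier transform. The slice basis vectors are the first two rows of
// the rotation matrix; `scale` maps image Fourier pixels to volume Fourier
// pixels (= padded volume size / image box).
// [[Rcpp::export]]
arma::cx_mat cpp_extract_slice(const arma::cx_cube& F, const arma::mat& R,
                               int box, double scale) {
  arma::cx_mat S(box, box);
  const double r0x = R(0, 0), r0y = R(0, 1), r0z = R(0, 2);
  const double r1x = R(1, 0), r1y = R(1, 1), r1z = R(1, 2);
  for (int j = 0; j < box; ++j) {
    const double ky = (j - box / 2) * scale;
    for (int i = 0; i < box; ++i) {
      const double kx = (i - box / 2) * scale;
      S(i, j) = tri_cx(F,
                       kx * r0x + ky * r1x,
                       kx * r0y + ky * r1y,
                       kx * r0z + ky * r1z);
    }
  }
  return S;
}

// Accumulate CTF-weighted slices into data/weight grids (Wiener-style
// direct Fourier inversion). slices are centered 2D FTs of the (shift
// corrected) particle images; ctfs the matching CTF arrays. Each Fourier
// pixel of a slice is spread to its 8 trilinear neighbours.
// [[Rcpp::export]]
List cpp_backproject(const arma::cx_cube& slices, const arma::cube& rots,
                     const arma::cube& ctfs, int P, double scale) {
  const int b = slices.n_rows;
  const int n = slices.n_slices;
  arma::cx_cube data(P, P, P, arma::fill::zeros);
  arma::cube weight(P, P, P, arma::fill::zeros);
  const double c = P / 2.0;
  for (int s = 0; s < n; ++s) {
    const arma::mat R = rots.slice(s);
    const double r0x = R(0, 0), r0y = R(0, 1), r0z = R(0, 2);
    const double r1x = R(1, 0), r1y = R(1, 1), r1z = R(1, 2);
    for (int j = 0; j < b; ++j) {
      const double ky = (j - b / 2) * scale;
      for (int i = 0; i < b; ++i) {
        const double kx = (i - b / 2) * scale;
        const double ctf = ctfs(i, j, s);
        const std::complex<double> val = ctf * slices(i, j, s);
        const double w2 = ctf * ctf;
        const double gx = kx * r0x + ky * r1x + c;
        const double gy = kx * r0y + ky * r1y + c;
        const double gz = kx * r0z + ky * r1z + c;
        const int x0 = (int)std::floor(gx);
        const int y0 = (int)std::floor(gy);
        const int z0 = (int)std::floor(gz);
        if (x0 < 0 || y0 < 0 || z0 < 0 || x0 >= P - 1 || y0 >= P - 1 || z0 >= P - 1)
          continue;
        const double fx = gx - x0, fy = gy - y0, fz = gz - z0;
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx) {
              const double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) * (dz ? fz : 1 - fz);
              data(x0 + dx, y0 + dy, z0 + dz) += w * val;
              weight(x0 + dx, y0 + dy, z0 + dz) += w * w2;
            }
      }
    }
  }
  return List::create(_["data"] = data, _["weight"] = weight);
}

// Trilinear sampling of a real volume at centered coordinates (n x 3
// matrix); points outside the grid evaluate to 0.
// [[Rcpp::export]]
arma::vec cpp_sample_volume(const arma::cube& V, const arma::mat& pts) {
  const int n = V.n_rows;
  const double c = n / 2.0;
  const int m = pts.n_rows;
  arma::vec out(m, arma::fill::zeros);
  for (int p = 0; p < m; ++p) {
    const double gx = pts(p, 0) + c, gy = pts(p, 1) + c, gz = pts(p, 2) + c;
    const int x0 = (int)std::floor(gx);
    const int y0 = (int)std::floor(gy);
    const int z0 = (int)std::floor(gz);
    if (x0 < 0 || y0 < 0 || z0 < 0 || x0 > n - 1 || y0 > n - 1 || z0 > n - 1)
      continue;
    const int x1 = x0 < n - 1 ? x0 + 1 : x0;
    const int y1 = y0 < n - 1 ? y0 + 1 : y0;
    const int z1 = z0 < n - 1 ? z0 + 1 : z0;
    const double fx = gx - x0, fy = gy - y0, fz = gz - z0;
    double v = 0.0;
    for (int dz = 0; dz < 2; ++dz)
      for (int dy = 0; dy < 2; ++dy)
        for (int dx = 0; dx < 2; ++dx)
          v += (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) * (dz ? fz : 1 - fz) *
               V(dx ? x1 : x0, dy ? y1 : y0, dz ? z1 : z0);
    out(p) = v;
  }
  return out;
}

// Local grid-search scorer. For every candidate rotation, extract the
// reference slice at the masked frequency list `kxy` (centered image
// Fourier-pixel coordinates, DC excluded), multiply by the CTF, and score
// normalized cross-correlation against the particle transform Xf at zero
// shift. For the best rotation, rescore over the phase-ramp columns of
// `ramps` (candidate shifts applied to the reference). Ties keep the
// earlier candidate, so callers order candidates by distance from the
// start pose. Returns 1-based indices.
// [[Rcpp::export]]
List cpp_refine(const arma::cx_cube& F, const arma::cube& rots,
                const arma::mat& kxy, const arma::cx_vec& Xf,
                const arma::vec& ctf, const arma::cx_mat& ramps,
                double scale) {
  const int nf = kxy.n_rows;
  const int nr = rots.n_slices;
  const double xnorm = std::sqrt(arma::accu(arma::square(arma::abs(Xf))));
  int best = 0;
  double best_score = -2.0;
  arma::cx_vec Pbest(nf);
  arma::cx_vec Pf(nf);
  for (int r = 0; r < nr; ++r) {
    const arma::mat R = rots.slice(r);
    const double r0x = R(0, 0), r0y = R(0, 1), r0z = R(0, 2);
    const double r1x = R(1, 0), r1y = R(1, 1), r1z = R(1, 2);
    std::complex<double> cross(0.0, 0.0);
    double pn = 0.0;
    for (int f = 0; f < nf; ++f) {
      const double kx = kxy(f, 0) * scale, ky = kxy(f, 1) * scale;
      std::complex<double> v = ctf(f) * tri_cx(F,
                                               kx * r0x + ky * r1x,
                                               kx * r0y + ky * r1y,
                                               kx * r0z + ky * r1z);
      Pf(f) = v;
      cross += std::conj(v) * Xf(f);
      pn += std::norm(v);
    }
    const double denom = std::sqrt(pn) * xnorm;
    const double score = denom > 0 ? cross.real() / denom : 0.0;
    if (score > best_score + 1e-12) {
      best_score = score;
      best = r;
      Pbest = Pf;
    }
  }
  // shift search for the winning rotation
  int best_shift = 0;
  double pn = arma::accu(arma::square(arma::abs(Pbest)));
  const double denom = std::sqrt(pn) * xnorm;
  double best_sscore = -2.0;
  for (arma::uword s = 0; s < ramps.n_cols; ++s) {
    std::complex<double> cross(0.0, 0.0);
    for (int f = 0; f < nf; ++f)
      cross += std::conj(Pbest(f) * ramps(f, s)) * Xf(f);
    const double score = denom > 0 ? cross.real() / denom : 0.0;
    if (score > best_sscore + 1e-12) {
      best_sscore = score;
      best_shift = s;
    }
  }
  return List::create(_["rot"] = best + 1, _["shift"] = best_shift + 1,
                      _["score"] = best_sscore);
}
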
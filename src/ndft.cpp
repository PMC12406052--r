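#include <Rcpp.h>
#include <complex>
#include <vector>

using namespace Rcpp;

// Exact non-uniform discrete Fourier transforms between a Cartesian image
// grid and arbitrary k-space locations.
//
// Conventions (shared with the R side):
//  * voxel coordinates are centred integers x in {-Nx/2, ..., Nx/2 - 1}
//    (x varying fastest, then y, then z — R array order);
//  * k-space coordinates are normalised cycles/FOV per axis in [-0.5, 0.5);
//  * forward kernel is exp(-2*pi*i * k . r), adjoint uses the conjugate.
//
// The inner voxel loops use complex phase recurrences (one complex multiply
// per voxel per sample) instead of calling exp() M*N times.

static inline std::complex<double> unit_phase(double frac) {
  // exp(-2*pi*i*frac)
  double a = -2.0 * M_PI * frac;
  return std::complex<double>(std::cos(a), std::sin(a));
}

// [[Rcpp::export]]
ComplexVector ndft_forward_cpp(ComplexVector img, IntegerVector dims,
                               NumericVector kx, NumericVector ky,
                               NumericVector kz) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int M = nx * ny * nz;
  const int N = kx.size();
  if (img.size() != M) stop("image length does not match dims");

  std::vector< std::complex<double> > f(M);
  for (int m = 0; m < M; ++m)
    f[m] = std::complex<double>(img[m].r, img[m].i);

  const int x0 = -(nx / 2), y0 = -(ny / 2), z0 = -(nz / 2);
  ComplexVector out(N);

  for (int n = 0; n < N; ++n) {
    const std::complex<double> sx = unit_phase(kx[n]);
    const std::complex<double> sy = unit_phase(ky[n]);
    const std::complex<double> sz = unit_phase(kz[n]);
    std::complex<double> wz = unit_phase(kz[n] * z0);
    std::complex<double> acc(0.0, 0.0);
    int m = 0;
    for (int z = 0; z < nz; ++z) {
      std::complex<double> wy = unit_phase(ky[n] * y0) * wz;
      for (int y = 0; y < ny; ++y) {
        std::complex<double> wx = unit_phase(kx[n] * x0) * wy;
        for (int x = 0; x < nx; ++x) {
          acc += f[m++] * wx;
          wx *= sx;
        }
        wy *= sy;
      }
      wz *= sz;
    }
    out[n].r = acc.real();
    out[n].i = acc.imag();
  }
  return out;
}

// [[Rcpp::export]]
ComplexVector ndft_adjoint_cpp(ComplexVector samples, IntegerVector dims,
                               NumericVector kx, NumericVector ky,
                               NumericVector kz) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int M = nx * ny * nz;
  const int N = kx.size();
  if (samples.size() != N) stop("sample length does not match k locations");

  std::vector< std::complex<double> > acc(M, std::complex<double>(0.0, 0.0));
  const int x0 = -(nx / 2), y0 = -(ny / 2), z0 = -(nz / 2);

  for (int n = 0; n < N; ++n) {
    const std::complex<double> yv(samples[n].r, samples[n].i);
    // conjugate kernel: exp(+2*pi*i*k.r)
    const std::complex<double> sx = std::conj(unit_phase(kx[n]));
    const std::complex<double> sy = std::conj(unit_phase(ky[n]));
    const std::complex<double> sz = std::conj(unit_phase(kz[n]));
    std::complex<double> wz = std::conj(unit_phase(kz[n] * z0));
    int m = 0;
    for (int z = 0; z < nz; ++z) {
      std::complex<double> wy = std::conj(unit_phase(ky[n] * y0)) * wz;
      for (int y = 0; y < ny; ++y) {
        std::complex<double> wx = std::conj(unit_phase(kx[n] * x0)) * wy;
        for (int x = 0; x < nx; ++x) {
          acc[m++] += yv * wx;
          wx *= sx;
        }
        wy *= sy;
      }
      wz *= sz;
    }
  }

  ComplexVector out(M);
  for (int m = 0; m < M; ++m) {
    out[m].r = acc[m].real();
    out[m].i = acc[m].imag();
  }
  return out;
}
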
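// Spectral finite-difference diffusion solve for homogeneous coefficients:
// mirror-pad laterally (Neumann modes), 2D FFT per depth slice, one
// tridiagonal solve in depth per lateral mode, inverse FFT. Exactly the
// 7-point FD system the sparse path assembles, solved mode-by-mode.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// [[Rcpp::export(name = ".fdSpectralSolveCpp")]]
Rcpp::NumericVector fd_spectral_solve(const Rcpp::NumericVector &Sarr,
                                      double D, double mu,
                                      double dx, double dz, double A) {
  Rcpp::IntegerVector dm = Sarr.attr("dim");
  const uword ny = dm[0], nx = dm[1], nz = dm[2];
  const uword my = 2 * ny, mx = 2 * nx;

  // mirrored source, FFT per slice
  cube S(const_cast<double *>(Sarr.begin()), ny, nx, nz, false, true);
  cx_cube F(my, mx, nz);
  mat slice_m(my, mx);
  for (uword k = 0; k < nz; ++k) {
    for (uword j = 0; j < my; ++j) {
      uword js = (j < ny) ? j : (2 * ny - 1 - j);
      for (uword i = 0; i < mx; ++i) {
        uword is = (i < nx) ? i : (2 * nx - 1 - i);
        slice_m(j, i) = S(js, is, k);
      }
    }
    F.slice(k) = fft2(slice_m);
  }

  // lateral mode eigenvalues
  vec lamy(my), lamx(mx);
  for (uword j = 0; j < my; ++j)
    lamy(j) = (2.0 - 2.0 * std::cos(2.0 * M_PI * j / my)) / (dx * dx);
  for (uword i = 0; i < mx; ++i)
    lamx(i) = (2.0 - 2.0 * std::cos(2.0 * M_PI * i / mx)) / (dx * dx);

  const double off = -D / (dz * dz);
  const double robin = (2.0 * D / (dz * dz)) / (1.0 + 4.0 * A * D / dz);
  const double d2 = D / (dz * dz);

  // Thomas solve in depth, vectorized over all lateral modes per slice
  mat base(my, mx);
  for (uword i = 0; i < mx; ++i)
    for (uword j = 0; j < my; ++j)
      base(j, i) = mu + D * (lamy(j) + lamx(i));
  cube cpr(my, mx, nz);  // c' is real: off-diagonal and diagonal are real
  cx_mat dprev(my, mx);
  mat cprev(my, mx), invden(my, mx);
  {
    mat b0 = base + d2 + robin;
    cprev = off / b0;
    cpr.slice(0) = cprev;
    dprev = F.slice(0) % conv_to<cx_mat>::from(1.0 / b0);
    F.slice(0) = dprev;
  }
  for (uword k = 1; k < nz; ++k) {
    mat bk = base + ((k == nz - 1) ? d2 : 2.0 * d2);
    invden = 1.0 / (bk - off * cprev);
    cprev = off * invden;
    cpr.slice(k) = cprev;
    dprev = (F.slice(k) - off * dprev) % conv_to<cx_mat>::from(invden);
    F.slice(k) = dprev;
  }
  for (sword k = (sword)nz - 2; k >= 0; --k)
    F.slice(k) -= conv_to<cx_mat>::from(cpr.slice(k)) % F.slice(k + 1);

  Rcpp::NumericVector out(ny * nx * nz);
  out.attr("dim") = Rcpp::IntegerVector::create(ny, nx, nz);
  cube phi(out.begin(), ny, nx, nz, false, true);
  for (uword k = 0; k < nz; ++k) {
    mat re = real(ifft2(F.slice(k)));
    phi.slice(k) = re.submat(0, 0, ny - 1, nx - 1);
  }
  return out;
}
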
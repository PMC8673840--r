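#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Solve the missed-event survivor matrix R(u) of an aggregated Markov class
// on a uniform grid. R satisfies the Volterra integro-differential equation
//
//   R'(u) = R(u) Qxx + int_0^{min(u, td)} R(u - v) K(v) dv,   R(0) = I,
//
// where Qxx is the within-class sub-generator and K(v) = Qxy exp(Qyy v) Qyx
// is the kernel of excursions into the other class that are shorter than the
// dead time td (and therefore undetected). The kernel is supplied
// pre-evaluated on the same grid (spacing h, m = td/h intervals). Integration
// uses a Heun predictor-corrector with trapezoidal convolution, O(h^2).
//
// Arguments: k class dimension (1 or 2), Qxx k x k, Kflat column-major array
// of (m+1) kernel matrices, h grid step (s), n_steps number of steps.
// Returns a numeric vector of (n_steps+1) matrices, column-major, to be given
// dim (k, k, n_steps+1) in R.
// [[Rcpp::export]]
NumericVector volterra_grid(int k, NumericMatrix Qxx, NumericVector Kflat,
                            double h, int n_steps, int m) {
  const int kk = k * k;
  std::vector<double> R((n_steps + 1) * kk, 0.0);
  for (int a = 0; a < k; ++a) R[a + a * k] = 1.0;  // R(0) = I

  std::vector<double> C(kk), F0(kk), Rp(kk), C1(kk), F1(kk);

  // matrix product helpers over flat storage (column-major k x k)
  auto matmul_into = [&](const double* A, const double* B, double* out,
                         double w, bool add) {
    for (int j = 0; j < k; ++j)
      for (int i = 0; i < k; ++i) {
        double s = 0.0;
        for (int l = 0; l < k; ++l) s += A[i + l * k] * B[l + j * k];
        if (add) out[i + j * k] += w * s; else out[i + j * k] = w * s;
      }
  };

  // trapezoidal convolution: C(u_i) = int R(u_i - v) K(v) dv over v grid,
  // with Rtop standing in for R at lag 0 (used with the predictor).
  auto conv = [&](int i, const double* Rtop, double* out) {
    std::fill(out, out + kk, 0.0);
    int jmax = i < m ? i : m;
    if (jmax < 1) {
      if (i >= 1 || m >= 1) { /* nothing: zero-width integral */ }
      return;
    }
    for (int j = 0; j <= jmax; ++j) {
      double w = (j == 0 || j == jmax) ? 0.5 * h : h;
      const double* Rlag = (j == 0) ? Rtop : &R[(i - j) * kk];
      matmul_into(Rlag, &Kflat[j * kk], out, w, true);
    }
  };

  for (int i = 0; i < n_steps; ++i) {
    const double* Ri = &R[i * kk];
    // F_i = R_i Qxx + C_i
    conv(i, Ri, C.data());
    matmul_into(Ri, &Qxx[0], F0.data(), 1.0, false);
    for (int a = 0; a < kk; ++a) F0[a] += C[a];
    // predictor
    for (int a = 0; a < kk; ++a) Rp[a] = Ri[a] + h * F0[a];
    // corrector slope at i+1 using the predictor for the lag-0 term
    conv(i + 1, Rp.data(), C1.data());
    matmul_into(Rp.data(), &Qxx[0], F1.data(), 1.0, false);
    for (int a = 0; a < kk; ++a) F1[a] += C1[a];
    double* Rn = &R[(i + 1) * kk];
    for (int a = 0; a < kk; ++a) Rn[a] = Ri[a] + 0.5 * h * (F0[a] + F1[a]);
  }

  NumericVector out(R.begin(), R.end());
  return out;
}
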
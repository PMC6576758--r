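#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Gather sliding windows of a channel-fastest (C, L, N) activation array
// into the (C*k, P*N) patch matrix consumed by the convolution GEMM.
// [[Rcpp::export]]
SEXP conv_im2col(NumericVector Z, int C, int L, int N, int k) {
  const int P = L - k + 1;
  const R_xlen_t collen = (R_xlen_t)C * k;
  SEXP out = PROTECT(Rf_allocMatrix(REALSXP, (int)collen, P * N));
  double *o = REAL(out);
  const double *z = Z.begin();
  for (int n = 0; n < N; ++n) {
    const double *zn = z + (R_xlen_t)n * C * L;
    double *on = o + (R_xlen_t)n * P * collen;
    for (int p = 0; p < P; ++p)
      std::memcpy(on + (R_xlen_t)p * collen, zn + (R_xlen_t)p * C,
                  collen * sizeof(double));
  }
  UNPROTECT(1);
  return out;
}

// Scatter-add the transpose-convolution of patch gradients back onto the
// (C, L, N) input layout (adjoint of conv_im2col).
// [[Rcpp::export]]
SEXP conv_col2im(NumericVector dXcol, int C, int L, int N, int k) {
  const int P = L - k + 1;
  const R_xlen_t collen = (R_xlen_t)C * k;
  SEXP out = PROTECT(Rf_allocVector(REALSXP, (R_xlen_t)C * L * N));
  double *o = REAL(out);
  std::memset(o, 0, (R_xlen_t)C * L * N * sizeof(double));
  const double *d = dXcol.begin();
  for (int n = 0; n < N; ++n) {
    double *on = o + (R_xlen_t)n * C * L;
    const double *dn = d + (R_xlen_t)n * P * collen;
    for (int p = 0; p < P; ++p) {
      const double *src = dn + (R_xlen_t)p * collen;
      double *dst = on + (R_xlen_t)p * C;
      for (R_xlen_t j = 0; j < collen; ++j) dst[j] += src[j];
    }
  }
  SEXP dim = PROTECT(Rf_allocVector(INTSXP, 3));
  INTEGER(dim)[0] = C; INTEGER(dim)[1] = L; INTEGER(dim)[2] = N;
  Rf_setAttrib(out, R_DimSymbol, dim);
  UNPROTECT(2);
  return out;
}

// Fused batchnorm forward over a channel-fastest (F, m) view.  Training
// mode uses batch statistics and returns updated running moments; inference
// uses the supplied running moments.  The backward pass reconstructs xhat
// from y, so only y and istd need caching.
// [[Rcpp::export]]
List bn_forward(NumericVector Z, int F, NumericVector gamma,
                NumericVector beta, NumericVector run_mean,
                NumericVector run_var, double eps, double momentum,
                bool training) {
  const R_xlen_t total = Z.size();
  const R_xlen_t m = total / F;
  SEXP y_s = PROTECT(Rf_allocVector(REALSXP, total));
  double *y = REAL(y_s);
  const double *z = Z.begin();
  NumericVector mu(F), var(F), istd(F);
  NumericVector new_rm = clone(run_mean), new_rv = clone(run_var);
  double *mup = mu.begin(), *varp = var.begin(), *istdp = istd.begin();
  if (training) {
    for (R_xlen_t j = 0; j < m; ++j) {
      const double *zj = z + j * F;
      for (int f = 0; f < F; ++f) mup[f] += zj[f];
    }
    for (int f = 0; f < F; ++f) mup[f] /= (double)m;
    for (R_xlen_t j = 0; j < m; ++j) {
      const double *zj = z + j * F;
      for (int f = 0; f < F; ++f) {
        double d = zj[f] - mup[f];
        varp[f] += d * d;
      }
    }
    for (int f = 0; f < F; ++f) {
      varp[f] /= (double)m;
      new_rm[f] = momentum * run_mean[f] + (1 - momentum) * mup[f];
      new_rv[f] = momentum * run_var[f] + (1 - momentum) * varp[f];
    }
  } else {
    for (int f = 0; f < F; ++f) { mup[f] = run_mean[f]; varp[f] = run_var[f]; }
  }
  std::vector<double> a(F), b(F);
  for (int f = 0; f < F; ++f) {
    istdp[f] = 1.0 / std::sqrt(varp[f] + eps);
    a[f] = gamma[f] * istdp[f];
    b[f] = beta[f] - a[f] * mup[f];
  }
  for (R_xlen_t j = 0; j < m; ++j) {
    const double *zj = z + j * F;
    double *yj = y + j * F;
    for (int f = 0; f < F; ++f) yj[f] = a[f] * zj[f] + b[f];
  }
  List out = List::create(_["y"] = y_s, _["istd"] = istd,
                          _["run_mean"] = new_rm, _["run_var"] = new_rv);
  UNPROTECT(1);
  return out;
}

// Batchnorm backward from dY and the forward outputs.
// [[Rcpp::export]]
List bn_backward(NumericVector dY, NumericVector Y, int F,
                 NumericVector gamma, NumericVector beta,
                 NumericVector istd) {
  const R_xlen_t total = dY.size();
  const R_xlen_t m = total / F;
  NumericVector dgamma(F), dbeta(F);
  SEXP dX_s = PROTECT(Rf_allocVector(REALSXP, total));
  double *dx = REAL(dX_s);
  const double *dy = dY.begin(), *y = Y.begin();
  double *dg = dgamma.begin(), *db = dbeta.begin();
  std::vector<double> ig(F);
  for (int f = 0; f < F; ++f)
    ig[f] = 1.0 / (gamma[f] == 0.0 ? 1e-12 : gamma[f]);
  for (R_xlen_t j = 0; j < m; ++j) {
    const double *dyj = dy + j * F, *yj = y + j * F;
    for (int f = 0; f < F; ++f) {
      dg[f] += dyj[f] * (yj[f] - beta[f]) * ig[f];
      db[f] += dyj[f];
    }
  }
  std::vector<double> s(F);
  for (int f = 0; f < F; ++f) s[f] = gamma[f] * istd[f] / (double)m;
  for (R_xlen_t j = 0; j < m; ++j) {
    const double *dyj = dy + j * F, *yj = y + j * F;
    double *dxj = dx + j * F;
    for (int f = 0; f < F; ++f) {
      double xh = (yj[f] - beta[f]) * ig[f];
      dxj[f] = s[f] * ((double)m * dyj[f] - db[f] - xh * dg[f]);
    }
  }
  List out = List::create(_["dX"] = dX_s, _["dgamma"] = dgamma,
                          _["dbeta"] = dbeta);
  UNPROTECT(1);
  return out;
}

// Fused ReLU + inverted dropout (training).  Returns the activation and the
// combined local gradient g with y = z * g, so backward is dZ = dY * g.
// Draws from R's RNG for reproducibility under set.seed().
// [[Rcpp::export]]
List relu_dropout_forward(NumericVector Z, double p) {
  const R_xlen_t total = Z.size();
  SEXP y_s = PROTECT(Rf_allocVector(REALSXP, total));
  SEXP g_s = PROTECT(Rf_allocVector(REALSXP, total));
  double *yp = REAL(y_s), *gp = REAL(g_s);
  const double *z = Z.begin();
  const double scale = (p > 0) ? 1.0 / (1.0 - p) : 1.0;
  if (p > 0) {
    // geometric-gap sampling: one RNG draw per dropped unit instead of one
    // per unit (deterministic under set.seed(), just a different stream use)
    for (R_xlen_t i = 0; i < total; ++i) {
      double gi = z[i] > 0 ? scale : 0.0;
      gp[i] = gi;
      yp[i] = z[i] * gi;
    }
    const double il1p = 1.0 / std::log1p(-p);
    R_xlen_t i = (R_xlen_t)std::floor(std::log(unif_rand()) * il1p);
    while (i < total) {
      gp[i] = 0.0;
      yp[i] = 0.0;
      i += 1 + (R_xlen_t)std::floor(std::log(unif_rand()) * il1p);
    }
  } else {
    for (R_xlen_t i = 0; i < total; ++i) {
      double gi = z[i] > 0 ? 1.0 : 0.0;
      gp[i] = gi;
      yp[i] = z[i] * gi;
    }
  }
  List out = List::create(_["y"] = y_s, _["g"] = g_s);
  UNPROTECT(2);
  return out;
}

// Elementwise product used for the relu/dropout backward.
// [[Rcpp::export]]
SEXP ew_mul(NumericVector a, NumericVector b) {
  const R_xlen_t n = a.size();
  SEXP out = PROTECT(Rf_allocVector(REALSXP, n));
  double *o = REAL(out);
  const double *ap = a.begin(), *bp = b.begin();
  for (R_xlen_t i = 0; i < n; ++i) o[i] = ap[i] * bp[i];
  UNPROTECT(1);
  return out;
}
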
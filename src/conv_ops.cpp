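// Low-level array kernels for the encoding models.
//
// Feature arrays use a channels-last layout (H, W, N, C): the (H, W) plane
// for a fixed (image n, channel c) is a contiguous H*W block, which keeps the
// inner loops over rows vectorizable and lets R reinterpret the same memory
// as an (H*W*N) x C matrix for 1x1 (channel-mixing) convolutions via BLAS.
//
// All spatial convolutions are cross-correlations with "same" zero padding
// and odd kernels centered at ((kh-1)/2, (kw-1)/2).

#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <algorithm>
#include <cmath>
#include <memory>

using namespace Rcpp;

static inline void corr_plane_acc(const double* __restrict__ x, double wgt,
                                  int H, int W, int dy, int dx,
                                  double* __restrict__ out) {
  // out[h, w] += wgt * x[h + dy, w + dx] over the in-bounds region
  const int h0 = std::max(0, -dy), h1 = std::min(H, H - dy);
  const int w0 = std::max(0, -dx), w1 = std::min(W, W - dx);
  const int len = h1 - h0;
  if (len <= 0) return;
  for (int w = w0; w < w1; ++w) {
    const double* __restrict__ xs = x + (std::size_t)(h0 + dy) + (std::size_t)H * (w + dx);
    double* __restrict__ os = out + (std::size_t)h0 + (std::size_t)H * w;
    for (int h = 0; h < len; ++h) os[h] += wgt * xs[h];
  }
}

static inline double corr_plane_dot(const double* __restrict__ x,
                                    const double* __restrict__ gy, int H,
                                    int W, int dy, int dx) {
  // sum over valid (h, w) of x[h + dy, w + dx] * gy[h, w]
  const int h0 = std::max(0, -dy), h1 = std::min(H, H - dy);
  const int w0 = std::max(0, -dx), w1 = std::min(W, W - dx);
  const int len = h1 - h0;
  if (len <= 0) return 0.0;
  double a0 = 0.0, a1 = 0.0, a2 = 0.0, a3 = 0.0;
  for (int w = w0; w < w1; ++w) {
    const double* __restrict__ xs = x + (std::size_t)(h0 + dy) + (std::size_t)H * (w + dx);
    const double* __restrict__ gs = gy + (std::size_t)h0 + (std::size_t)H * w;
    int h = 0;
    for (; h + 4 <= len; h += 4) {
      a0 += xs[h] * gs[h];
      a1 += xs[h + 1] * gs[h + 1];
      a2 += xs[h + 2] * gs[h + 2];
      a3 += xs[h + 3] * gs[h + 3];
    }
    for (; h < len; ++h) a0 += xs[h] * gs[h];
  }
  return a0 + a1 + a2 + a3;
}

static void get_dims(const NumericVector& a, int* d, int nd) {
  IntegerVector dim = a.attr("dim");
  if (dim.size() != nd) stop("array has %d dimensions, expected %d", (int)dim.size(), nd);
  for (int i = 0; i < nd; ++i) d[i] = dim[i];
}

// [[Rcpp::export]]
NumericVector cc_conv1_forward(NumericVector x, NumericVector k) {
  // x: (H, W, N) single-channel images; k: (kh, kw, K) -> (H, W, N, K)
  int dx_[3], dk_[3];
  get_dims(x, dx_, 3);
  get_dims(k, dk_, 3);
  const int H = dx_[0], W = dx_[1], N = dx_[2];
  const int kh = dk_[0], kw = dk_[1], K = dk_[2];
  const int cy = (kh - 1) / 2, cx = (kw - 1) / 2;
  const std::size_t HW = (std::size_t)H * W;
  NumericVector out((std::size_t)HW * N * K);
  out.attr("dim") = IntegerVector::create(H, W, N, K);
  const double* xp = x.begin();
  const double* kp = k.begin();
  double* op = out.begin();
  for (int kk = 0; kk < K; ++kk) {
    const double* kk_p = kp + (std::size_t)kh * kw * kk;
    for (int n = 0; n < N; ++n) {
      const double* xn = xp + HW * n;
      double* on = op + HW * ((std::size_t)N * kk + n);
      for (int j = 0; j < kw; ++j)
        for (int i = 0; i < kh; ++i) {
          double w = kk_p[i + kh * j];
          if (w != 0.0) corr_plane_acc(xn, w, H, W, i - cy, j - cx, on);
        }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cc_conv1_gradk(NumericVector x, NumericVector gy, int kh, int kw) {
  // gradient of sum(gy * conv1(x, k)) w.r.t. k; gy: (H, W, N, K)
  int dx_[3], dg_[4];
  get_dims(x, dx_, 3);
  get_dims(gy, dg_, 4);
  const int H = dx_[0], W = dx_[1], N = dx_[2], K = dg_[3];
  if (dg_[0] != H || dg_[1] != W || dg_[2] != N) stop("cc_conv1_gradk: shape mismatch");
  const int cy = (kh - 1) / 2, cx = (kw - 1) / 2;
  const std::size_t HW = (std::size_t)H * W;
  NumericVector gk((std::size_t)kh * kw * K);
  gk.attr("dim") = IntegerVector::create(kh, kw, K);
  const double* xp = x.begin();
  const double* gp = gy.begin();
  double* gkp = gk.begin();
  for (int kk = 0; kk < K; ++kk) {
    double* gk_k = gkp + (std::size_t)kh * kw * kk;
    for (int n = 0; n < N; ++n) {
      const double* xn = xp + HW * n;
      const double* gn = gp + HW * ((std::size_t)N * kk + n);
      for (int j = 0; j < kw; ++j)
        for (int i = 0; i < kh; ++i)
          gk_k[i + kh * j] += corr_plane_dot(xn, gn, H, W, i - cy, j - cx);
    }
  }
  return gk;
}

// [[Rcpp::export]]
NumericVector cc_dwconv_forward(NumericVector x, NumericVector k) {
  // depthwise: x (H, W, N, C), k (kh, kw, C) -> (H, W, N, C)
  int dx_[4], dk_[3];
  get_dims(x, dx_, 4);
  get_dims(k, dk_, 3);
  const int H = dx_[0], W = dx_[1], N = dx_[2], C = dx_[3];
  const int kh = dk_[0], kw = dk_[1];
  if (dk_[2] != C) stop("cc_dwconv_forward: channel mismatch");
  const int cy = (kh - 1) / 2, cx = (kw - 1) / 2;
  const std::size_t HW = (std::size_t)H * W;
  NumericVector out((std::size_t)HW * N * C);
  out.attr("dim") = IntegerVector::create(H, W, N, C);
  const double* xp = x.begin();
  const double* kp = k.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c) {
    const double* kc = kp + (std::size_t)kh * kw * c;
    for (int n = 0; n < N; ++n) {
      const double* xn = xp + HW * ((std::size_t)N * c + n);
      double* on = op + HW * ((std::size_t)N * c + n);
      for (int j = 0; j < kw; ++j)
        for (int i = 0; i < kh; ++i) {
          double w = kc[i + kh * j];
          if (w != 0.0) corr_plane_acc(xn, w, H, W, i - cy, j - cx, on);
        }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cc_dwconv_gradk(NumericVector x, NumericVector gy, int kh, int kw) {
  int dx_[4], dg_[4];
  get_dims(x, dx_, 4);
  get_dims(gy, dg_, 4);
  const int H = dx_[0], W = dx_[1], N = dx_[2], C = dx_[3];
  for (int i = 0; i < 4; ++i)
    if (dg_[i] != dx_[i]) stop("cc_dwconv_gradk: shape mismatch");
  const int cy = (kh - 1) / 2, cx = (kw - 1) / 2;
  const std::size_t HW = (std::size_t)H * W;
  NumericVector gk((std::size_t)kh * kw * C);
  gk.attr("dim") = IntegerVector::create(kh, kw, C);
  const double* xp = x.begin();
  const double* gp = gy.begin();
  double* gkp = gk.begin();
  for (int c = 0; c < C; ++c) {
    double* gk_c = gkp + (std::size_t)kh * kw * c;
    for (int n = 0; n < N; ++n) {
      const double* xn = xp + HW * ((std::size_t)N * c + n);
      const double* gn = gp + HW * ((std::size_t)N * c + n);
      for (int j = 0; j < kw; ++j)
        for (int i = 0; i < kh; ++i)
          gk_c[i + kh * j] += corr_plane_dot(xn, gn, H, W, i - cy, j - cx);
    }
  }
  return gk;
}

// [[Rcpp::export]]
List cc_maxpool2(NumericVector x) {
  // 2x2 max pool, stride 2; x (H, W, N, C) with H, W even
  int d[4];
  get_dims(x, d, 4);
  const int H = d[0], W = d[1], N = d[2], C = d[3];
  if (H % 2 || W % 2) stop("cc_maxpool2: H and W must be even");
  const int H2 = H / 2, W2 = W / 2;
  const std::size_t HW = (std::size_t)H * W, HW2 = (std::size_t)H2 * W2;
  const std::size_t NC = (std::size_t)N * C;
  NumericVector y(HW2 * NC);
  IntegerVector idx(HW2 * NC);  // linear index into x (1-based) of the max
  y.attr("dim") = IntegerVector::create(H2, W2, N, C);
  idx.attr("dim") = IntegerVector::create(H2, W2, N, C);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  for (std::size_t b = 0; b < NC; ++b) {
    const double* xb = xp + HW * b;
    double* yb = yp + HW2 * b;
    int* ib = ip + HW2 * b;
    for (int w = 0; w < W2; ++w)
      for (int h = 0; h < H2; ++h) {
        std::size_t o00 = (std::size_t)(2 * h) + (std::size_t)H * (2 * w);
        std::size_t best = o00;
        double v = xb[o00];
        std::size_t cand[3] = {o00 + 1, o00 + (std::size_t)H, o00 + (std::size_t)H + 1};
        for (int t = 0; t < 3; ++t)
          if (xb[cand[t]] > v) { v = xb[cand[t]]; best = cand[t]; }
        yb[h + (std::size_t)H2 * w] = v;
        ib[h + (std::size_t)H2 * w] = (int)(HW * b + best) + 1;
      }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cc_maxpool2_bwd(NumericVector gy, IntegerVector idx, int H, int W) {
  int d[4];
  get_dims(gy, d, 4);
  const int N = d[2], C = d[3];
  NumericVector gx((std::size_t)H * W * N * C);
  gx.attr("dim") = IntegerVector::create(H, W, N, C);
  const double* gp = gy.begin();
  const int* ip = idx.begin();
  double* xp = gx.begin();
  const std::size_t n = gy.size();
  for (std::size_t i = 0; i < n; ++i) xp[(std::size_t)ip[i] - 1] += gp[i];
  return gx;
}

static void dgemm_wrap(bool ta, bool tb, int m, int n, int k, const double* A,
                       int lda, const double* B, int ldb, double* C, int ldc) {
  const char* TA = ta ? "T" : "N";
  const char* TB = tb ? "T" : "N";
  const double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)(TA, TB, &m, &n, &k, &one, A, &lda, B, &ldb, &zero, C, &ldc
                  FCONE FCONE);
}

// Fused training step for the minimodel head on frozen conv1 features.
//
// a0:  (H, W, B, C1) frozen conv1 features for one minibatch
// resp: (B) observed responses
// head: depthwise spatial conv (k2) -> 1x1 mix -> batch norm (train mode,
//       batch statistics) -> ReLU -> factorized readout -> ELU(z)+1 rate ->
//       Poisson loss (mean over the batch).
// Returns the loss, gradients for every parameter, and the batch-norm batch
// statistics so the caller can maintain running averages.
// [[Rcpp::export]]
List mm_step(NumericVector a0, NumericVector resp, NumericVector k2,
             NumericMatrix mix, NumericVector gamma, NumericVector beta,
             NumericVector wx, NumericVector wy, NumericVector wc,
             double offset, double bn_eps) {
  int d[4];
  get_dims(a0, d, 4);
  const int H = d[0], W = d[1], B = d[2], C1 = d[3];
  const int M = mix.ncol();
  if (mix.nrow() != C1) stop("mm_step: mix must be C1 x M");
  if (wy.size() != H || wx.size() != W) stop("mm_step: readout length mismatch");
  if (resp.size() != B) stop("mm_step: response length mismatch");
  int dk[3];
  get_dims(k2, dk, 3);
  const int kh = dk[0], kw = dk[1];
  const std::size_t HW = (std::size_t)H * W;
  const std::size_t P = HW * B;  // rows of the (pixels x channels) matrices

  // forward: depthwise conv
  NumericVector S = cc_dwconv_forward(a0, k2);

  // 1x1 mix: U (P x M) = S (P x C1) %*% mix
  std::unique_ptr<double[]> Ubuf(new double[P * (std::size_t)M]);
  double* U = Ubuf.get();
  dgemm_wrap(false, false, (int)P, M, C1, S.begin(), (int)P, mix.begin(), C1,
             U, (int)P);

  // batch norm (training mode) + ReLU
  std::vector<double> mu(M), inv(M), varb(M);
  std::unique_ptr<double[]> Ybuf(new double[P * (std::size_t)M]);
  double* Y = Ybuf.get();
  for (int m = 0; m < M; ++m) {
    const double* u = U + P * (std::size_t)m;
    double s = 0.0, sq = 0.0;
    for (std::size_t i = 0; i < P; ++i) { s += u[i]; sq += u[i] * u[i]; }
    const double mean = s / (double)P;
    double v = sq / (double)P - mean * mean;
    if (v < 0) v = 0;
    mu[m] = mean; varb[m] = v; inv[m] = 1.0 / std::sqrt(v + bn_eps);
    const double g = gamma[m], b = beta[m], iv = inv[m];
    double* y = Y + P * (std::size_t)m;
    for (std::size_t i = 0; i < P; ++i) y[i] = g * (u[i] - mean) * iv + b;
  }

  // readout
  std::vector<double> spat(HW);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) spat[h + (std::size_t)H * w] = wy[h] * wx[w];
  NumericMatrix pooled(B, M);
  for (int m = 0; m < M; ++m)
    for (int n = 0; n < B; ++n) {
      const double* y = Y + HW * ((std::size_t)B * m + n);
      double acc = 0.0;
      for (std::size_t p = 0; p < HW; ++p)
        acc += spat[p] * std::max(y[p], 0.0);
      pooled(n, m) = acc;
    }
  std::vector<double> z(B), rate(B), dz(B);
  double loss = 0.0;
  for (int n = 0; n < B; ++n) {
    double zz = offset;
    for (int m = 0; m < M; ++m) zz += wc[m] * pooled(n, m);
    z[n] = zz;
    double r = (zz > 0.0) ? zz + 1.0 : std::exp(zz);
    if (r < 1e-12) r = 1e-12;
    rate[n] = r;
    loss += r - resp[n] * std::log(r);
    const double drate = (zz > 0.0) ? 1.0 : r;  // d(ELU(z)+1)/dz
    dz[n] = (1.0 - resp[n] / r) * drate / (double)B;
  }
  loss /= (double)B;

  // backward: readout parameters
  NumericVector dwc(M), dwx(W), dwy(H);
  double doffset = 0.0;
  NumericMatrix dpooled(B, M);
  for (int n = 0; n < B; ++n) doffset += dz[n];
  for (int m = 0; m < M; ++m) {
    double acc = 0.0;
    for (int n = 0; n < B; ++n) {
      acc += pooled(n, m) * dz[n];
      dpooled(n, m) = dz[n] * wc[m];
    }
    dwc[m] = acc;
  }

  // G[h, w] = sum_{n, m} relu(Y) * dpooled ; dY = (Y > 0) * spat * dpooled;
  // batch-norm backward statistics accumulated in the same sweep
  std::vector<double> G(HW, 0.0);
  std::unique_ptr<double[]> dYbuf(new double[P * (std::size_t)M]);
  double* dY = dYbuf.get();
  NumericVector dgamma(M), dbeta(M);
  for (int m = 0; m < M; ++m) {
    const double mean = mu[m], iv = inv[m];
    double sg = 0.0, sgx = 0.0;
    for (int n = 0; n < B; ++n) {
      const double dp = dpooled(n, m);
      const std::size_t off = HW * ((std::size_t)B * m + n);
      const double* y = Y + off;
      const double* u = U + off;
      double* gy = dY + off;
      for (std::size_t p = 0; p < HW; ++p) {
        const double ind = (y[p] > 0.0) ? 1.0 : 0.0;
        const double val = spat[p] * ind * dp;
        G[p] += y[p] * ind * dp;
        gy[p] = val;
        sg += val;
        sgx += val * (u[p] - mean) * iv;
      }
    }
    dgamma[m] = sgx; dbeta[m] = sg;
  }
  for (int w = 0; w < W; ++w) {
    double acc = 0.0;
    for (int h = 0; h < H; ++h) acc += wy[h] * G[h + (std::size_t)H * w];
    dwx[w] = acc;
  }
  for (int h = 0; h < H; ++h) {
    double acc = 0.0;
    for (int w = 0; w < W; ++w) acc += wx[w] * G[h + (std::size_t)H * w];
    dwy[h] = acc;
  }

  // batch-norm backward (in place on dY -> dU)
  for (int m = 0; m < M; ++m) {
    const double* u = U + P * (std::size_t)m;
    double* gy = dY + P * (std::size_t)m;
    const double mean = mu[m], iv = inv[m], g = gamma[m];
    const double m1 = dbeta[m] / (double)P, m2 = dgamma[m] / (double)P;
    const double giv = g * iv;
    for (std::size_t i = 0; i < P; ++i) {
      const double xh = (u[i] - mean) * iv;
      gy[i] = giv * (gy[i] - m1 - xh * m2);
    }
  }

  // mix and depthwise kernel gradients
  NumericMatrix dmix(C1, M);
  dgemm_wrap(true, false, C1, M, (int)P, S.begin(), (int)P, dY, (int)P,
             dmix.begin(), C1);
  NumericVector dS(Rcpp::no_init((R_xlen_t)(P * C1)));
  dS.attr("dim") = IntegerVector::create(H, W, B, C1);
  dgemm_wrap(false, true, (int)P, C1, M, dY, (int)P, mix.begin(), C1,
             dS.begin(), (int)P);
  NumericVector dk2 = cc_dwconv_gradk(a0, dS, kh, kw);

  NumericVector bmu(M), bvar(M);
  for (int m = 0; m < M; ++m) { bmu[m] = mu[m]; bvar[m] = varb[m]; }
  return List::create(
      _["loss"] = loss, _["dk2"] = dk2, _["dmix"] = dmix,
      _["dgamma"] = dgamma, _["dbeta"] = dbeta, _["dwx"] = dwx,
      _["dwy"] = dwy, _["dwc"] = dwc, _["doffset"] = doffset,
      _["batch_mean"] = bmu, _["batch_var"] = bvar);
}

// Evaluation-mode forward pass of the minimodel head (running batch-norm
// statistics). Returns predicted rates and, optionally, the per-channel
// spatially pooled activations used by the invariance analyses.
// [[Rcpp::export]]
List mm_forward(NumericVector a0, NumericVector k2, NumericMatrix mix,
                NumericVector gamma, NumericVector beta, NumericVector rmean,
                NumericVector rvar, NumericVector wx, NumericVector wy,
                NumericVector wc, double offset, double bn_eps,
                bool want_pooled) {
  int d[4];
  get_dims(a0, d, 4);
  const int H = d[0], W = d[1], B = d[2], C1 = d[3];
  const int M = mix.ncol();
  const std::size_t HW = (std::size_t)H * W;
  const std::size_t P = HW * B;

  NumericVector S = cc_dwconv_forward(a0, k2);
  std::unique_ptr<double[]> Ubuf(new double[P * (std::size_t)M]);
  double* U = Ubuf.get();
  dgemm_wrap(false, false, (int)P, M, C1, S.begin(), (int)P, mix.begin(), C1,
             U, (int)P);
  std::vector<double> spat(HW);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) spat[h + (std::size_t)H * w] = wy[h] * wx[w];

  NumericMatrix pooled(B, M);
  for (int m = 0; m < M; ++m) {
    const double iv = 1.0 / std::sqrt(rvar[m] + bn_eps);
    const double g = gamma[m], b = beta[m], mean = rmean[m];
    for (int n = 0; n < B; ++n) {
      const double* u = U + HW * ((std::size_t)B * m + n);
      double acc = 0.0;
      for (std::size_t p = 0; p < HW; ++p) {
        const double y = g * (u[p] - mean) * iv + b;
        acc += spat[p] * std::max(y, 0.0);
      }
      pooled(n, m) = acc;
    }
  }
  NumericVector rate(B), z(B);
  for (int n = 0; n < B; ++n) {
    double zz = offset;
    for (int m = 0; m < M; ++m) zz += wc[m] * pooled(n, m);
    z[n] = zz;
    rate[n] = (zz > 0.0) ? zz + 1.0 : std::exp(zz);
  }
  if (want_pooled)
    return List::create(_["rate"] = rate, _["z"] = z, _["pooled"] = pooled);
  return List::create(_["rate"] = rate, _["z"] = z);
}
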
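// CPU kernels for the SegNet encoder-decoder: zero-copy shifted-GEMM
// convolution fused with batch-norm + ReLU, 2x2 max pooling with stored
// indices, max-unpooling, factor-2 bilinear up-sampling (half-pixel
// convention), and an 8-connected component labeller used by the biometry
// module.
//
// Arrays cross the R boundary as double; convolution arithmetic runs in
// float32 (ample for network training, ~2x the GEMM throughput of double).
// A 3x3 "same" convolution is computed as nine strided sgemm accumulations
// of the flat (H*W x Cin) image against the per-offset (Cin x Cout) weight
// slices; rows whose flat shift wraps across a column boundary are
// corrected by a small scalar fix-up, so no im2col panel is ever
// materialized. Float conversions live in persistent scratch buffers so
// repeated calls do not pay allocation costs every mini-batch.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <queue>
#include <vector>
using namespace Rcpp;
using namespace arma;

#ifdef __GLIBC__
#include <malloc.h>
#endif

// Training churns hundreds of MB of activation arrays per mini-batch;
// with glibc's default mmap threshold every large vector is mapped and
// unmapped again, and page-fault time dwarfs the arithmetic. Raising the
// thresholds keeps the arena resident across batches.
// [[Rcpp::export(name = "cpp_tune_allocator")]]
bool cpp_tune_allocator() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 1 << 30);
  mallopt(M_TRIM_THRESHOLD, 1 << 30);
  return true;
#else
  return false;
#endif
}

extern "C" void sgemm_(const char*, const char*, const int*, const int*,
                       const int*, const float*, const float*, const int*,
                       const float*, const int*, const float*, float*,
                       const int*);

static void sgemm(char ta, char tb, int m, int n, int k, float alpha,
                  const float* A, int lda, const float* B, int ldb,
                  float beta, float* C, int ldc) {
  sgemm_(&ta, &tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta, C, &ldc);
}

static std::vector<float> g_xf, g_y, g_dz, g_dx;

static float* scratch(std::vector<float>& buf, size_t n) {
  if (buf.size() < n) buf.resize(n);
  return buf.data();
}

static void get_dim4(const NumericVector& x, int d[4]) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  for (int i = 0; i < 4; i++) d[i] = dm[i];
}

// Offset geometry for one kernel tap of a 3x3 "same" convolution on a
// column-major H x W plane: flat shift s, the valid flat row range
// [r0, r1], and the wrapped row (h = 0 or H-1) needing scalar correction.
struct Tap { int dh, dw, s, r0, r1, hfix; };

static Tap tap_geometry(int off, int H, int W) {
  Tap t;
  t.dh = off % 3 - 1; t.dw = off / 3 - 1;
  t.s = t.dh + H * t.dw;
  const int HW = H * W;
  t.r0 = std::max(0, -t.s);
  t.r1 = HW - 1 - std::max(0, t.s);
  t.hfix = (t.dh == -1) ? 0 : (t.dh == 1 ? H - 1 : -1);
  return t;
}

// 3x3 convolution of one image: Y (HW x Cout, ldc HW) = conv(X) + bias.
// X is (HW x Cin) with column stride HW. Wf is (9*Cin x Cout) laid out as
// (kh, kw, ci) rows, i.e. tap index kh + 3*kw at stride 9 per channel.
static void conv3x3_fwd_img(const float* X, int H, int W, int Cin, int Cout,
                            const float* Wf, const float* bias, float* Y) {
  const int HW = H * W;
  for (int co = 0; co < Cout; co++)
    std::fill(Y + (size_t)co * HW, Y + (size_t)(co + 1) * HW, bias[co]);
  std::vector<float> Wk(Cin * Cout);
  for (int off = 0; off < 9; off++) {
    const Tap t = tap_geometry(off, H, W);
    const int kidx = (t.dh + 1) + 3 * (t.dw + 1);
    for (int co = 0; co < Cout; co++)
      for (int ci = 0; ci < Cin; ci++)
        Wk[ci + Cin * co] = Wf[kidx + 9 * ci + 9 * Cin * co];
    const int m = t.r1 - t.r0 + 1;
    if (m <= 0) continue;
    sgemm('N', 'N', m, Cout, Cin, 1.0f, X + t.r0 + t.s, HW,
          Wk.data(), Cin, 1.0f, Y + t.r0, HW);
    if (t.hfix >= 0) {
      // rows h = hfix wrongly pulled the wrapped pixel q = r + s
      for (int w = 0; w < W; w++) {
        const int r = t.hfix + H * w;
        if (r < t.r0 || r > t.r1) continue;
        const int q = r + t.s;
        for (int co = 0; co < Cout; co++) {
          float acc = 0.0f;
          for (int ci = 0; ci < Cin; ci++)
            acc += X[q + (size_t)ci * HW] * Wk[ci + Cin * co];
          Y[r + (size_t)co * HW] -= acc;
        }
      }
    }
  }
}

// Adjoint pieces for one image: accumulates dX (+=), dW (+=), db (+=).
static void conv3x3_bwd_img(const float* X, const float* dZ, int H, int W,
                            int Cin, int Cout, const float* Wf,
                            float* dX, float* dWf, float* db) {
  const int HW = H * W;
  std::vector<float> Wk(Cin * Cout), dWk(Cin * Cout);
  for (int co = 0; co < Cout; co++) {
    const float* col = dZ + (size_t)co * HW;
    float acc = 0.0f;
    for (int j = 0; j < HW; j++) acc += col[j];
    db[co] += acc;
  }
  for (int off = 0; off < 9; off++) {
    const Tap t = tap_geometry(off, H, W);
    const int kidx = (t.dh + 1) + 3 * (t.dw + 1);
    for (int co = 0; co < Cout; co++)
      for (int ci = 0; ci < Cin; ci++)
        Wk[ci + Cin * co] = Wf[kidx + 9 * ci + 9 * Cin * co];
    const int m = t.r1 - t.r0 + 1;
    if (m <= 0) continue;
    // dX[r + s] += dZ[r] * Wk^T
    sgemm('N', 'T', m, Cin, Cout, 1.0f, dZ + t.r0, HW,
          Wk.data(), Cin, 1.0f, dX + t.r0 + t.s, HW);
    // dWk += X[r + s]^T * dZ[r]
    sgemm('T', 'N', Cin, Cout, m, 1.0f, X + t.r0 + t.s, HW,
          dZ + t.r0, HW, 0.0f, dWk.data(), Cin);
    if (t.hfix >= 0) {
      for (int w = 0; w < W; w++) {
        const int r = t.hfix + H * w;
        if (r < t.r0 || r > t.r1) continue;
        const int q = r + t.s;
        for (int co = 0; co < Cout; co++) {
          const float g = dZ[r + (size_t)co * HW];
          for (int ci = 0; ci < Cin; ci++) {
            dX[q + (size_t)ci * HW] -= g * Wk[ci + Cin * co];
            dWk[ci + Cin * co] -= X[q + (size_t)ci * HW] * g;
          }
        }
      }
    }
    for (int co = 0; co < Cout; co++)
      for (int ci = 0; ci < Cin; ci++)
        dWf[kidx + 9 * ci + 9 * Cin * co] += dWk[ci + Cin * co];
  }
}

// Convolution of the whole batch into the float scratch g_y.
// Returns pointer to g_y holding (HW x Cout) per image, contiguous.
static float* conv_batch(const double* x, int H, int W, int Cin, int N,
                         const NumericVector& w, const NumericVector& b) {
  IntegerVector dw_ = w.attr("dim");
  const int K = dw_[0], Cout = dw_[3];
  const size_t HW = (size_t)H * W;
  fvec wf(w.size());
  for (int i = 0; i < w.size(); i++) wf[i] = (float)w[i];
  fvec bf(b.size());
  for (int i = 0; i < b.size(); i++) bf[i] = (float)b[i];
  float* yf = scratch(g_y, HW * Cout * N);
  float* xf = scratch(g_xf, HW * Cin * N);
  for (size_t i = 0; i < HW * Cin * N; i++) xf[i] = (float)x[i];
  if (K == 1) {
    fmat Wmat(wf.memptr(), Cin, Cout, false, true);
    for (int n = 0; n < N; n++) {
      fmat X(xf + (size_t)n * HW * Cin, HW, Cin, false, true);
      fmat Y(yf + (size_t)n * HW * Cout, HW, Cout, false, true);
      Y = X * Wmat;
      Y.each_row() += bf.t();
    }
  } else {
    for (int n = 0; n < N; n++)
      conv3x3_fwd_img(xf + (size_t)n * HW * Cin, H, W, Cin, Cout,
                      wf.memptr(), bf.memptr(), yf + (size_t)n * HW * Cout);
  }
  return yf;
}

// Fused convolution -> batch-norm -> ReLU forward pass.
// bn = FALSE gives a plain (optionally ReLU-ed) convolution; training
// selects batch statistics (returned for the running-average update),
// otherwise rmean/rvar are used.
// [[Rcpp::export(name = "cpp_convbnrelu_fwd")]]
List cpp_convbnrelu_fwd(NumericVector x, NumericVector w, NumericVector b,
                        NumericVector gamma, NumericVector beta,
                        NumericVector rmean, NumericVector rvar,
                        double eps, bool training, bool bn, bool relu) {
  int d[4]; get_dim4(x, d);
  const int H = d[0], W = d[1], Cin = d[2], N = d[3];
  IntegerVector dw_ = w.attr("dim");
  if (dw_.size() != 4 || dw_[0] != dw_[1] || dw_[2] != Cin)
    stop("weight must be (K, K, Cin, Cout) with Cin matching input");
  const int Cout = dw_[3];
  const size_t HW = (size_t)H * W;
  float* yf = conv_batch(x.begin(), H, W, Cin, N, w, b);

  NumericVector a((size_t)HW * Cout * N);
  a.attr("dim") = IntegerVector::create(H, W, Cout, N);
  if (!bn) {
    double* ap = a.begin();
    const size_t tot = HW * Cout * N;
    if (relu) for (size_t i = 0; i < tot; i++) ap[i] = yf[i] > 0 ? yf[i] : 0.0;
    else for (size_t i = 0; i < tot; i++) ap[i] = yf[i];
    return List::create(_["a"] = a);
  }

  NumericVector xhat((size_t)HW * Cout * N);
  xhat.attr("dim") = IntegerVector::create(H, W, Cout, N);
  NumericVector bmean(Cout), bvar(Cout), invstd(Cout);
  const size_t M = HW * N;
  for (int c = 0; c < Cout; c++) {
    double mu, var;
    if (training) {
      double s1 = 0, s2 = 0;
      for (int n = 0; n < N; n++) {
        const float* p = yf + HW * (c + (size_t)Cout * n);
        for (size_t j = 0; j < HW; j++) { s1 += p[j]; s2 += (double)p[j] * p[j]; }
      }
      mu = s1 / M;
      var = s2 / M - mu * mu;
      if (var < 0) var = 0;
    } else {
      mu = rmean[c]; var = rvar[c];
    }
    const double is = 1.0 / std::sqrt(var + eps);
    const double g = gamma[c], bb = beta[c];
    bmean[c] = mu; bvar[c] = var; invstd[c] = is;
    for (int n = 0; n < N; n++) {
      const size_t off = HW * (c + (size_t)Cout * n);
      const float* p = yf + off;
      double* xh = xhat.begin() + off;
      double* ap = a.begin() + off;
      for (size_t j = 0; j < HW; j++) {
        const double v = (p[j] - mu) * is;
        xh[j] = v;
        const double act = g * v + bb;
        ap[j] = (relu && act < 0) ? 0.0 : act;
      }
    }
  }
  return List::create(_["a"] = a, _["xhat"] = xhat, _["invstd"] = invstd,
                      _["batch_mean"] = bmean, _["batch_var"] = bvar);
}

// Fused backward pass of conv -> batch-norm -> ReLU.
// da is the gradient at the block output; a/xhat/invstd come from the
// forward cache; x is the block input. Returns dx and parameter gradients.
// [[Rcpp::export(name = "cpp_convbnrelu_bwd")]]
List cpp_convbnrelu_bwd(NumericVector da, NumericVector a, NumericVector xhat,
                        NumericVector gamma, NumericVector invstd,
                        NumericVector x, NumericVector w,
                        bool bn, bool relu) {
  int d[4]; get_dim4(da, d);
  const int H = d[0], W = d[1], Cout = d[2], N = d[3];
  int dxd[4]; get_dim4(x, dxd);
  const int Cin = dxd[2];
  IntegerVector dw_ = w.attr("dim");
  const int K = dw_[0];
  const size_t HW = (size_t)H * W;
  const size_t M = HW * N;

  // gradient wrt the convolution output z, in float scratch
  float* dz = scratch(g_dz, HW * Cout * N);
  NumericVector dgamma(Cout), dbeta(Cout);
  const double* dap = da.begin();
  if (bn) {
    const double* ap = a.begin();
    const double* xh = xhat.begin();
    for (int c = 0; c < Cout; c++) {
      double sd = 0, sdx = 0;
      for (int n = 0; n < N; n++) {
        const size_t off = HW * (c + (size_t)Cout * n);
        for (size_t j = 0; j < HW; j++) {
          const size_t i = off + j;
          const double g = (relu && ap[i] <= 0) ? 0.0 : dap[i];
          sd += g; sdx += g * xh[i];
        }
      }
      dgamma[c] = sdx; dbeta[c] = sd;
      const double gg = gamma[c], is = invstd[c];
      const double c1 = sd / M, c2 = sdx / M;
      for (int n = 0; n < N; n++) {
        const size_t off = HW * (c + (size_t)Cout * n);
        float* dzp = dz + off;
        for (size_t j = 0; j < HW; j++) {
          const size_t i = off + j;
          const double g = (relu && ap[i] <= 0) ? 0.0 : dap[i];
          dzp[j] = (float)(gg * is * (g - c1 - xh[i] * c2));
        }
      }
    }
  } else {
    const double* ap = a.begin();
    const size_t tot = HW * Cout * N;
    if (relu) for (size_t i = 0; i < tot; i++)
      dz[i] = (ap[i] <= 0) ? 0.0f : (float)dap[i];
    else for (size_t i = 0; i < tot; i++) dz[i] = (float)dap[i];
  }

  fvec wf(w.size());
  for (int i = 0; i < w.size(); i++) wf[i] = (float)w[i];
  float* xf = scratch(g_xf, HW * Cin * N);
  const double* xp = x.begin();
  for (size_t i = 0; i < HW * Cin * N; i++) xf[i] = (float)xp[i];
  float* dxf = scratch(g_dx, HW * Cin * N);
  std::fill(dxf, dxf + HW * Cin * N, 0.0f);
  fvec dWf(w.size(), fill::zeros);
  fvec dbf(Cout, fill::zeros);
  NumericVector dx((size_t)HW * Cin * N);
  dx.attr("dim") = IntegerVector::create(H, W, Cin, N);

  if (K == 1) {
    fmat Wmat(wf.memptr(), Cin, Cout, false, true);
    fmat dW(dWf.memptr(), Cin, Cout, false, true);
    for (int n = 0; n < N; n++) {
      fmat X(xf + (size_t)n * HW * Cin, HW, Cin, false, true);
      fmat dZ(dz + (size_t)n * HW * Cout, HW, Cout, false, true);
      fmat dX(dxf + (size_t)n * HW * Cin, HW, Cin, false, true);
      dW += X.t() * dZ;
      dbf += sum(dZ, 0).t();
      dX = dZ * Wmat.t();
    }
  } else {
    for (int n = 0; n < N; n++)
      conv3x3_bwd_img(xf + (size_t)n * HW * Cin,
                      dz + (size_t)n * HW * Cout, H, W, Cin, Cout,
                      wf.memptr(), dxf + (size_t)n * HW * Cin,
                      dWf.memptr(), dbf.memptr());
  }
  double* dxp = dx.begin();
  for (size_t i = 0; i < HW * Cin * N; i++) dxp[i] = dxf[i];
  NumericVector dWr(dWf.n_elem);
  for (size_t i = 0; i < dWf.n_elem; i++) dWr[i] = dWf[i];
  dWr.attr("dim") = IntegerVector::create(K, K, Cin, Cout);
  NumericVector dbr(Cout);
  for (int i = 0; i < Cout; i++) dbr[i] = dbf[i];
  return List::create(_["dx"] = dx, _["dw"] = dWr, _["db"] = dbr,
                      _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export(name = "cpp_maxpool2_fwd")]]
List cpp_maxpool2_fwd(NumericVector x) {
  int d[4]; get_dim4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("max pooling requires even spatial dims");
  const int Ho = H / 2, Wo = W / 2;
  const double* xp = x.begin();
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx(y.size());  // 0-based flat index into the H*W plane
  double* yp = y.begin(); int* ip = idx.begin();
  size_t o = 0;
  for (int cn = 0; cn < C * N; cn++) {
    const double* plane = xp + (size_t)cn * H * W;
    for (int wo = 0; wo < Wo; wo++) {
      for (int ho = 0; ho < Ho; ho++, o++) {
        const int h = 2 * ho, w = 2 * wo;
        int best = h + H * w;
        double bv = plane[best];
        const int cand[3] = {h + 1 + H * w, h + H * (w + 1), h + 1 + H * (w + 1)};
        for (int k = 0; k < 3; k++)
          if (plane[cand[k]] > bv) { bv = plane[cand[k]]; best = cand[k]; }
        yp[o] = bv; ip[o] = best;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = "cpp_maxpool2_bwd")]]
NumericVector cpp_maxpool2_bwd(IntegerVector idx, NumericVector dy, int H, int W) {
  int d[4]; get_dim4(dy, d);
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  NumericVector dx((size_t)H * W * C * N);
  double* dxp = dx.begin();
  const double* dyp = dy.begin(); const int* ip = idx.begin();
  size_t o = 0;
  for (int cn = 0; cn < C * N; cn++) {
    double* plane = dxp + (size_t)cn * H * W;
    for (int j = 0; j < Ho * Wo; j++, o++) plane[ip[o]] += dyp[o];
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}

// [[Rcpp::export(name = "cpp_unpool2_fwd")]]
NumericVector cpp_unpool2_fwd(NumericVector x, IntegerVector idx, int H, int W) {
  int d[4]; get_dim4(x, d);
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  if (idx.size() != x.size()) stop("indices must match input shape");
  NumericVector y((size_t)H * W * C * N);
  double* yp = y.begin();
  const double* xp = x.begin(); const int* ip = idx.begin();
  size_t o = 0;
  for (int cn = 0; cn < C * N; cn++) {
    double* plane = yp + (size_t)cn * H * W;
    for (int j = 0; j < Ho * Wo; j++, o++) plane[ip[o]] = xp[o];
  }
  y.attr("dim") = IntegerVector::create(H, W, C, N);
  return y;
}

// [[Rcpp::export(name = "cpp_unpool2_bwd")]]
NumericVector cpp_unpool2_bwd(NumericVector dy, IntegerVector idx, int Ho, int Wo) {
  int d[4]; get_dim4(dy, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  NumericVector dx((size_t)Ho * Wo * C * N);
  double* dxp = dx.begin();
  const double* dyp = dy.begin(); const int* ip = idx.begin();
  size_t o = 0;
  for (int cn = 0; cn < C * N; cn++) {
    const double* plane = dyp + (size_t)cn * H * W;
    for (int j = 0; j < Ho * Wo; j++, o++) dxp[o] = plane[ip[o]];
  }
  dx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return dx;
}

// Separable factor-2 bilinear up-sampling with half-pixel centers
// (src = (i + 0.5) / 2 - 0.5, edges clamped): along each axis
// out[2i] = 0.25 in[i-1] + 0.75 in[i], out[2i+1] = 0.75 in[i] + 0.25 in[i+1].
// [[Rcpp::export(name = "cpp_upsample_bilinear2_fwd")]]
NumericVector cpp_upsample_bilinear2_fwd(NumericVector x) {
  int d[4]; get_dim4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * C * N);
  double* yp = y.begin(); const double* xp = x.begin();
  std::vector<double> rowbuf((size_t)Ho * W);  // rows upsampled, cols pending
  for (int cn = 0; cn < C * N; cn++) {
    const double* in = xp + (size_t)cn * H * W;
    double* rb = rowbuf.data();
    for (int w = 0; w < W; w++) {
      const double* c = in + (size_t)w * H;
      double* o = rb + (size_t)w * Ho;
      for (int i = 0; i < H; i++) {
        const double prev = c[i > 0 ? i - 1 : 0];
        const double next = c[i < H - 1 ? i + 1 : H - 1];
        o[2 * i] = 0.25 * prev + 0.75 * c[i];
        o[2 * i + 1] = 0.75 * c[i] + 0.25 * next;
      }
    }
    double* out = yp + (size_t)cn * Ho * Wo;
    for (int w = 0; w < W; w++) {
      const double* prev = rb + (size_t)(w > 0 ? w - 1 : 0) * Ho;
      const double* cur = rb + (size_t)w * Ho;
      const double* next = rb + (size_t)(w < W - 1 ? w + 1 : W - 1) * Ho;
      double* o0 = out + (size_t)(2 * w) * Ho;
      double* o1 = out + (size_t)(2 * w + 1) * Ho;
      for (int i = 0; i < Ho; i++) {
        o0[i] = 0.25 * prev[i] + 0.75 * cur[i];
        o1[i] = 0.75 * cur[i] + 0.25 * next[i];
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return y;
}

// Adjoint of the separable up-sampler (exact transpose of the linear map).
// [[Rcpp::export(name = "cpp_upsample_bilinear2_bwd")]]
NumericVector cpp_upsample_bilinear2_bwd(NumericVector dy, int H, int W) {
  int d[4]; get_dim4(dy, d);
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  if (Ho != 2 * H || Wo != 2 * W) stop("gradient shape does not match factor 2");
  NumericVector dx((size_t)H * W * C * N);
  double* dxp = dx.begin(); const double* dyp = dy.begin();
  std::vector<double> colbuf((size_t)Ho * W);  // cols reduced, rows pending
  for (int cn = 0; cn < C * N; cn++) {
    const double* in = dyp + (size_t)cn * Ho * Wo;
    double* cb = colbuf.data();
    std::fill(cb, cb + (size_t)Ho * W, 0.0);
    for (int w = 0; w < W; w++) {
      const double* g0 = in + (size_t)(2 * w) * Ho;
      const double* g1 = in + (size_t)(2 * w + 1) * Ho;
      double* prev = cb + (size_t)(w > 0 ? w - 1 : 0) * Ho;
      double* cur = cb + (size_t)w * Ho;
      double* next = cb + (size_t)(w < W - 1 ? w + 1 : W - 1) * Ho;
      for (int i = 0; i < Ho; i++) {
        prev[i] += 0.25 * g0[i];
        cur[i] += 0.75 * g0[i] + 0.75 * g1[i];
        next[i] += 0.25 * g1[i];
      }
    }
    double* out = dxp + (size_t)cn * (size_t)H * W;
    for (int w = 0; w < W; w++) {
      const double* c = cb + (size_t)w * Ho;
      double* o = out + (size_t)w * H;
      for (int i = 0; i < H; i++) {
        const double g0 = c[2 * i], g1 = c[2 * i + 1];
        o[i] += 0.75 * g0 + 0.75 * g1;
        if (i > 0) o[i - 1] += 0.25 * g0; else o[0] += 0.25 * g0;
        if (i < H - 1) o[i + 1] += 0.25 * g1; else o[H - 1] += 0.25 * g1;
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}

// 8-connected component labelling of a binary matrix (BFS, column-major
// scan order).
// [[Rcpp::export(name = "cpp_label_components8")]]
IntegerMatrix cpp_label_components8(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int w = 0; w < W; w++) {
    for (int h = 0; h < H; h++) {
      if (mask(h, w) == 0 || lab(h, w) != 0) continue;
      lab(h, w) = ++next;
      q.push(std::make_pair(h, w));
      while (!q.empty()) {
        int ch = q.front().first, cw = q.front().second; q.pop();
        for (int dw = -1; dw <= 1; dw++) {
          for (int dh = -1; dh <= 1; dh++) {
            const int nh = ch + dh, nw = cw + dw;
            if (nh < 0 || nh >= H || nw < 0 || nw >= W) continue;
            if (mask(nh, nw) != 0 && lab(nh, nw) == 0) {
              lab(nh, nw) = next;
              q.push(std::make_pair(nh, nw));
            }
          }
        }
      }
    }
  }
  return lab;
}
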
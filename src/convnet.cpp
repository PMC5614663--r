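// Low-level convolution / pooling kernels.
//
// Layout conventions (all column-major, matching R arrays):
//   activations x : (H, W, C, N)
//   conv kernels w: (kh, kw, Cin, Cout)
// Convolutions use explicit zero padding and floor output sizing:
//   Hout = (H + 2*pad - kh) / stride + 1.
// Pooling uses ceil-mode output sizing with windows clipped to the
// feature map (Caffe convention), which maps 32 -> 16 -> 8 -> 4 for
// window 3 / stride 2. Average pooling divides by the clipped window
// size.
//
// The conv GEMMs (im2col) run in single precision: activations never
// leave [0, 1]-scale ranges and SGD is insensitive to float rounding,
// while sgemm roughly halves the time per batch. Results are returned
// as doubles. An optional fused ReLU avoids extra full-size copies on
// the R side; conv_backward re-masks the gradient from the post-ReLU
// output it is handed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int conv_out(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

static inline int pool_out(int in, int window, int stride) {
  // ceil((in - window) / stride) + 1
  int num = in - window;
  return (num + stride - 1) / stride + 1;
}

// Gather the padded receptive fields of every output location into a
// K x (Ho*Wo*N) float matrix, K = kh*kw*Cin. Column order: ho fastest,
// then wo, then image index n. Row order matches the column-major
// layout of the kernel array (kh fastest, then kw, then cin).
static arma::fmat im2col(const double* x, int H, int W, int C, int N,
                         int kh, int kw, int stride, int pad,
                         int Ho, int Wo) {
  const int K = kh * kw * C;
  arma::fmat col(K, (arma::uword)Ho * Wo * N, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const double* xn = x + (size_t)n * H * W * C;
    for (int wo = 0; wo < Wo; ++wo) {
      const int w0 = wo * stride - pad;
      for (int ho = 0; ho < Ho; ++ho) {
        const int h0 = ho * stride - pad;
        float* colc = col.colptr(((arma::uword)n * Wo + wo) * Ho + ho);
        int r = 0;
        for (int c = 0; c < C; ++c) {
          const double* xc = xn + (size_t)c * H * W;
          for (int j = 0; j < kw; ++j) {
            const int w = w0 + j;
            if (w < 0 || w >= W) { r += kh; continue; }
            const double* xcol = xc + (size_t)w * H;
            const int i0 = std::max(0, -h0), i1 = std::min(kh, H - h0);
            for (int i = i0; i < i1; ++i)
              colc[r + i] = (float)xcol[h0 + i];
            r += kh;
          }
        }
      }
    }
  }
  return col;
}

static arma::fmat as_fmat(const double* p, int nrow, int ncol) {
  arma::fmat m(nrow, ncol);
  float* dst = m.memptr();
  const size_t total = (size_t)nrow * ncol;
  for (size_t i = 0; i < total; ++i) dst[i] = (float)p[i];
  return m;
}

// [[Rcpp::export]]
NumericVector conv_forward_cpp(NumericVector x, NumericVector w,
                               NumericVector b, int stride, int pad,
                               bool relu = false) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Co = wd[3];
  if (Cin != C)
    stop("conv_forward: input has %d channels, kernel expects %d", C, Cin);
  const int Ho = conv_out(H, kh, stride, pad);
  const int Wo = conv_out(W, kw, stride, pad);
  if (Ho < 1 || Wo < 1) stop("conv_forward: input too small for kernel");
  const int K = kh * kw * C;

  arma::fmat col = im2col(x.begin(), H, W, C, N, kh, kw, stride, pad, Ho, Wo);
  arma::fmat Wm = as_fmat(w.begin(), K, Co);
  arma::fmat Y = Wm.t() * col;                 // Co x (Ho*Wo*N)

  NumericVector y((R_xlen_t)Ho * Wo * Co * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  double* yp = y.begin();
  const bool has_b = b.size() > 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < Co; ++c) {
      const float bc = has_b ? (float)b[c] : 0.0f;
      double* dst = yp + (size_t)Ho * Wo * (c + (size_t)Co * n);
      const arma::uword base = (arma::uword)n * Wo * Ho;
      for (int wo = 0; wo < Wo; ++wo) {
        const float* src = Y.memptr() +
          (size_t)(base + (arma::uword)wo * Ho) * Co + c;
        for (int ho = 0; ho < Ho; ++ho) {
          float v = src[(size_t)ho * Co] + bc;
          if (relu && v < 0.0f) v = 0.0f;
          dst[ho + (size_t)Ho * wo] = (double)v;
        }
      }
    }
  return y;
}

// y is the layer OUTPUT as returned by conv_forward_cpp (post-ReLU when
// relu = true); dy is masked by y > 0 internally in that case.
// [[Rcpp::export]]
List conv_backward_cpp(NumericVector x, NumericVector w, NumericVector y,
                       NumericVector dy, int stride, int pad,
                       bool relu = false) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Co = wd[3];
  const int Ho = yd[0], Wo = yd[1];
  const int K = kh * kw * C;

  // dY in the same column ordering as im2col, ReLU-masked on the fly
  arma::fmat dY(Co, (arma::uword)Ho * Wo * N);
  const double* dyp = dy.begin();
  const double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < Co; ++c) {
      const size_t off = (size_t)Ho * Wo * (c + (size_t)Co * n);
      const double* src = dyp + off;
      const double* ysrc = yp + off;
      const arma::uword base = (arma::uword)n * Wo * Ho;
      for (int wo = 0; wo < Wo; ++wo) {
        float* dst = dY.memptr() +
          (size_t)(base + (arma::uword)wo * Ho) * Co + c;
        for (int ho = 0; ho < Ho; ++ho) {
          double g = src[ho + (size_t)Ho * wo];
          if (relu && ysrc[ho + (size_t)Ho * wo] <= 0.0) g = 0.0;
          dst[(size_t)ho * Co] = (float)g;
        }
      }
    }

  arma::fmat col = im2col(x.begin(), H, W, C, N, kh, kw, stride, pad, Ho, Wo);
  arma::fmat Wm = as_fmat(w.begin(), K, Co);

  NumericVector dw((R_xlen_t)K * Co), db(Co);
  dw.attr("dim") = wd;
  {
    arma::fmat dWf = col * dY.t();             // K x Co
    const float* src = dWf.memptr();
    double* dst = dw.begin();
    for (size_t i = 0; i < (size_t)K * Co; ++i) dst[i] = (double)src[i];
    arma::fvec dbv = arma::sum(dY, 1);
    for (int c = 0; c < Co; ++c) db[c] = (double)dbv[c];
  }

  // dx via col2im scatter-add of Wm * dY
  arma::fmat dcol = Wm * dY;                   // K x (Ho*Wo*N)
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = xd;
  double* dxp = dx.begin();
  for (int n = 0; n < N; ++n) {
    double* dxn = dxp + (size_t)n * H * W * C;
    for (int wo = 0; wo < Wo; ++wo) {
      const int w0 = wo * stride - pad;
      for (int ho = 0; ho < Ho; ++ho) {
        const int h0 = ho * stride - pad;
        const float* dc = dcol.colptr(((arma::uword)n * Wo + wo) * Ho + ho);
        int r = 0;
        for (int c = 0; c < C; ++c) {
          double* dxc = dxn + (size_t)c * H * W;
          for (int j = 0; j < kw; ++j) {
            const int wcol = w0 + j;
            if (wcol < 0 || wcol >= W) { r += kh; continue; }
            double* dxcol = dxc + (size_t)wcol * H;
            const int i0 = std::max(0, -h0), i1 = std::min(kh, H - h0);
            for (int i = i0; i < i1; ++i)
              dxcol[h0 + i] += (double)dc[r + i];
            r += kh;
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// kind: 0 = max, 1 = average
// [[Rcpp::export]]
List pool_forward_cpp(NumericVector x, int window, int stride, int kind) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (window > H || window > W) stop("pool_forward: window exceeds input size");
  const int Ho = pool_out(H, window, stride), Wo = pool_out(W, window, stride);

  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(kind == 0 ? y.size() : 0);
  if (kind == 0) idx.attr("dim") = y.attr("dim");

  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* plane = xp + (size_t)H * W * (c + (size_t)C * n);
      const size_t obase = (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        const int ws = wo * stride, we = std::min(ws + window, W);
        for (int ho = 0; ho < Ho; ++ho) {
          const int hs = ho * stride, he = std::min(hs + window, H);
          const size_t o = obase + ho + (size_t)Ho * wo;
          if (kind == 0) {
            double best = plane[hs + (size_t)H * ws];
            int besti = hs + H * ws;
            for (int wq = ws; wq < we; ++wq)
              for (int hq = hs; hq < he; ++hq) {
                const double v = plane[hq + (size_t)H * wq];
                if (v > best) { best = v; besti = hq + H * wq; }
              }
            yp[o] = best;
            idx[o] = besti;
          } else {
            double s = 0.0;
            for (int wq = ws; wq < we; ++wq)
              for (int hq = hs; hq < he; ++hq)
                s += plane[hq + (size_t)H * wq];
            yp[o] = s / ((he - hs) * (we - ws));
          }
        }
      }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector pool_backward_cpp(NumericVector dy, IntegerVector idx,
                                IntegerVector xdim, int window, int stride,
                                int kind) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1];

  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = xdim;
  double* dxp = dx.begin();
  const double* dyp = dy.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* plane = dxp + (size_t)H * W * (c + (size_t)C * n);
      const size_t obase = (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        const int ws = wo * stride, we = std::min(ws + window, W);
        for (int ho = 0; ho < Ho; ++ho) {
          const int hs = ho * stride, he = std::min(hs + window, H);
          const size_t o = obase + ho + (size_t)Ho * wo;
          if (kind == 0) {
            plane[idx[o]] += dyp[o];
          } else {
            const double g = dyp[o] / ((he - hs) * (we - ws));
            for (int wq = ws; wq < we; ++wq)
              for (int hq = hs; hq < he; ++hq)
                plane[hq + (size_t)H * wq] += g;
          }
        }
      }
    }
  return dx;
}
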
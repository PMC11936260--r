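// Fused conv -> ReLU -> max-pool kernels for the compact two-convolution
// classifier. Convolutions are valid (no padding), stride 1; pooling uses
// non-overlapping windows (stride = size) with floor division, which is what
// pins the 256x256 -> 8x48x48 -> 16x8x8 -> 1024 shape chain.
//
// Layout conventions (match R's column-major array semantics):
//   images    : H x W x C x N numeric array
//   weights   : (k*k*C) x K matrix; column f is the filter, ordered so that
//               dim(w) <- c(k, k, C, K) recovers the kernel stack in R
//   im2col P  : (Ho*Wo) x (k*k*C); row index op = oy + Ho*ox
//
// Arithmetic is single precision internally (standard for CNN training);
// inputs/outputs cross the R boundary as doubles.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col(const float* x, int H, int W, int C,
                   int k, arma::fmat& P) {
  const int Ho = H - k + 1, Wo = W - k + 1;
  for (int c = 0; c < C; ++c) {
    const float* xc = x + (size_t)c * H * W;
    for (int b = 0; b < k; ++b) {
      for (int a = 0; a < k; ++a) {
        float* col = P.colptr(a + k * b + k * k * c);
        for (int ox = 0; ox < Wo; ++ox) {
          const float* src = xc + (size_t)(ox + b) * H + a;
          std::copy(src, src + Ho, col + (size_t)ox * Ho);
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv_relu_pool_fwd")]]
List conv_relu_pool_fwd(NumericVector x, NumericMatrix w, NumericVector b,
                        int k, int pool, bool want_act = false,
                        NumericVector mask = NumericVector(0)) {
  IntegerVector xd = x.attr("dim");
  if (xd.size() != 4) stop("input must be a 4-d array (H, W, C, N)");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H - k + 1, Wo = W - k + 1;
  if (Ho <= 0 || Wo <= 0) stop("kernel larger than input plane");
  const int Hp = Ho / pool, Wp = Wo / pool;
  if (Hp <= 0 || Wp <= 0) stop("pool window larger than feature map");
  const int K = w.ncol();
  if (w.nrow() != k * k * C) stop("weight rows must equal k*k*C");

  std::vector<float> xf(x.begin(), x.end());
  arma::fmat Wf(w.nrow(), K);
  std::copy(w.begin(), w.end(), Wf.memptr());
  arma::frowvec bf(K);
  for (int f = 0; f < K; ++f) bf[f] = (float)b[f];

  NumericVector out((size_t)Hp * Wp * K * N);
  out.attr("dim") = IntegerVector::create(Hp, Wp, K, N);
  IntegerVector arg((size_t)Hp * Wp * K * N);
  arg.attr("dim") = IntegerVector::create(Hp, Wp, K, N);
  NumericVector act(0);
  if (want_act) {
    act = NumericVector((size_t)Ho * Wo * K * N);
    act.attr("dim") = IntegerVector::create(Ho, Wo, K, N);
  }

  const bool use_mask = mask.size() > 0;
  if (use_mask && mask.size() != (R_xlen_t)Ho * Wo * K * N)
    stop("dropout mask must match the conv output grid");
  arma::fmat P(Ho * Wo, k * k * C);
  arma::fmat Conv(Ho * Wo, K);
  for (int n = 0; n < N; ++n) {
    im2col(xf.data() + (size_t)n * H * W * C, H, W, C, k, P);
    Conv = P * Wf;
    Conv.each_row() += bf;
    if (use_mask) {
      const double* mn = mask.begin() + (size_t)n * Ho * Wo * K;
      float* cp = Conv.memptr();
      for (size_t i = 0; i < (size_t)Ho * Wo * K; ++i) cp[i] *= (float)mn[i];
    }
    double* on = out.begin() + (size_t)n * Hp * Wp * K;
    int* an = arg.begin() + (size_t)n * Hp * Wp * K;
    for (int f = 0; f < K; ++f) {
      const float* cf = Conv.colptr(f);
      for (int px = 0; px < Wp; ++px) {
        for (int py = 0; py < Hp; ++py) {
          float best = -std::numeric_limits<float>::infinity();
          int besti = 0;
          for (int ox = px * pool; ox < (px + 1) * pool; ++ox) {
            const float* colseg = cf + (size_t)ox * Ho + py * pool;
            for (int dy = 0; dy < pool; ++dy) {
              if (colseg[dy] > best) {
                best = colseg[dy];
                besti = (py * pool + dy) + Ho * ox;
              }
            }
          }
          on[(size_t)py + Hp * px + (size_t)Hp * Wp * f] =
              best > 0.f ? best : 0.f;
          an[(size_t)py + Hp * px + (size_t)Hp * Wp * f] = besti;
        }
      }
      if (want_act) {
        double* af = act.begin() + (size_t)n * Ho * Wo * K + (size_t)f * Ho * Wo;
        for (size_t i = 0; i < (size_t)Ho * Wo; ++i)
          af[i] = cf[i] > 0.f ? cf[i] : 0.f;
      }
    }
  }
  if (want_act) return List::create(_["out"] = out, _["argmax"] = arg,
                                    _["act"] = act);
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".conv_relu_pool_bwd")]]
List conv_relu_pool_bwd(NumericVector x, NumericMatrix w, NumericVector dout,
                        IntegerVector arg, NumericVector out,
                        int k, int pool, bool need_dx = false,
                        NumericVector mask = NumericVector(0)) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H - k + 1, Wo = W - k + 1;
  const int Hp = Ho / pool, Wp = Wo / pool;
  const int K = w.ncol();

  std::vector<float> xf(x.begin(), x.end());
  arma::fmat Wf(w.nrow(), K);
  std::copy(w.begin(), w.end(), Wf.memptr());

  arma::fmat dW(k * k * C, K, arma::fill::zeros);
  arma::fvec db(K, arma::fill::zeros);
  NumericVector dx(0);
  if (need_dx) {
    dx = NumericVector((size_t)H * W * C * N);
    dx.attr("dim") = IntegerVector::create(H, W, C, N);
  }

  arma::fmat P(Ho * Wo, k * k * C);
  arma::fmat dConv(Ho * Wo, K);
  arma::fmat dXcols;
  const bool use_mask = mask.size() > 0;
  for (int n = 0; n < N; ++n) {
    dConv.zeros();
    const double* dn = dout.begin() + (size_t)n * Hp * Wp * K;
    const int* an = arg.begin() + (size_t)n * Hp * Wp * K;
    const double* on = out.begin() + (size_t)n * Hp * Wp * K;
    const double* mn = use_mask ?
      mask.begin() + (size_t)n * Ho * Wo * K : (const double*)nullptr;
    for (int f = 0; f < K; ++f) {
      float* dcf = dConv.colptr(f);
      const size_t off = (size_t)Hp * Wp * f;
      const size_t moff = (size_t)Ho * Wo * f;
      for (size_t i = 0; i < (size_t)Hp * Wp; ++i) {
        // ReLU gate: the pooled value is max(ReLU(mask * conv)); gradient
        // reaches the argmax only when that value is strictly positive,
        // scaled by the dropout mask value there.
        if (on[off + i] > 0.0) {
          float g = (float)dn[off + i];
          if (use_mask) g *= (float)mn[moff + an[off + i]];
          dcf[an[off + i]] += g;
        }
      }
      db[f] += arma::accu(dConv.col(f));
    }
    im2col(xf.data() + (size_t)n * H * W * C, H, W, C, k, P);
    dW += P.t() * dConv;
    if (need_dx) {
      dXcols = dConv * Wf.t();  // (Ho*Wo) x (k*k*C)
      double* dxn = dx.begin() + (size_t)n * H * W * C;
      for (int c = 0; c < C; ++c) {
        double* dxc = dxn + (size_t)c * H * W;
        for (int bcol = 0; bcol < k; ++bcol) {
          for (int a = 0; a < k; ++a) {
            const float* col = dXcols.colptr(a + k * bcol + k * k * c);
            for (int ox = 0; ox < Wo; ++ox) {
              double* dst = dxc + (size_t)(ox + bcol) * H + a;
              const float* src = col + (size_t)ox * Ho;
              for (int oy = 0; oy < Ho; ++oy) dst[oy] += src[oy];
            }
          }
        }
      }
    }
  }

  NumericMatrix dWr(k * k * C, K);
  std::copy(dW.begin(), dW.end(), dWr.begin());
  NumericVector dbr(K);
  for (int f = 0; f < K; ++f) dbr[f] = db[f];
  if (need_dx) return List::create(_["dw"] = dWr, _["db"] = dbr, _["dx"] = dx);
  return List::create(_["dw"] = dWr, _["db"] = dbr);
}
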
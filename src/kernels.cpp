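// Numerical kernels for the segmentation network and mask geometry.
// Tensor layout throughout: column-major R arrays dim (H, W, C, N).
// Convolution weights: dim (k, k, Cin, Cout); same padding with dilation.
// Patch matrices use the (H*W) x (k*k*Cin) layout so every inner loop
// reads and writes contiguous memory.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() == 3) { // promote single image to batch of 1
    IntegerVector d4(4);
    d4[0] = d[0]; d4[1] = d[1]; d4[2] = d[2]; d4[3] = 1;
    return d4;
  }
  if (d.size() != 4) stop("expected a 3-d or 4-d array");
  return d;
}

// Gather patches of one image into M (H*W rows, k*k*Cin cols), dilation d.
// Column index: kr + k*kc + k*k*ci; row index: h + H*w.
static void im2col(const double* x, int H, int W, int C,
                   int k, int dil, arma::mat& M) {
  const int pad = dil * (k - 1) / 2;
  for (int ci = 0; ci < C; ++ci) {
    const double* xc = x + (size_t)H * W * ci;
    for (int kc = 0; kc < k; ++kc) {
      for (int kr = 0; kr < k; ++kr) {
        const int r0 = kr * dil - pad, c0 = kc * dil - pad;
        double* dst = M.colptr(kr + k * kc + k * k * ci);
        const int h0 = std::max(0, -r0), h1 = std::min(H, H - r0);
        for (int w = 0; w < W; ++w, dst += H) {
          const int cc = w + c0;
          if (cc < 0 || cc >= W || h0 >= h1) {
            std::fill(dst, dst + H, 0.0);
          } else {
            if (h0 > 0) std::fill(dst, dst + h0, 0.0);
            std::copy(xc + (size_t)H * cc + h0 + r0,
                      xc + (size_t)H * cc + h1 + r0, dst + h0);
            if (h1 < H) std::fill(dst + h1, dst + H, 0.0);
          }
        }
      }
    }
  }
}

// Scatter-add the patch-matrix gradient back onto one input image.
static void col2im(const arma::mat& M, int H, int W, int C,
                   int k, int dil, double* dx) {
  const int pad = dil * (k - 1) / 2;
  for (int ci = 0; ci < C; ++ci) {
    double* xc = dx + (size_t)H * W * ci;
    for (int kc = 0; kc < k; ++kc) {
      for (int kr = 0; kr < k; ++kr) {
        const int r0 = kr * dil - pad, c0 = kc * dil - pad;
        const double* src = M.colptr(kr + k * kc + k * k * ci);
        const int h0 = std::max(0, -r0), h1 = std::min(H, H - r0);
        for (int w = 0; w < W; ++w, src += H) {
          const int cc = w + c0;
          if (cc < 0 || cc >= W || h0 >= h1) continue;
          double* dst = xc + (size_t)H * cc + r0;
          for (int h = h0; h < h1; ++h) dst[h] += src[h];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2dForward")]]
NumericVector conv2dForward(NumericVector x, NumericVector w,
                            NumericVector bias, int dilation) {
  IntegerVector xd = dims4(x);
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (wd[1] != k) stop("kernel must be square");
  if (Cin != C) stop("input channel mismatch");
  if (k % 2 == 0) stop("kernel size must be odd");
  NumericVector y((size_t)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat Wm(w.begin(), (size_t)k * k * Cin, Cout, false, true);
  arma::rowvec bv(bias.begin(), Cout, false, true);
  arma::mat M((size_t)H * W, (size_t)k * k * Cin);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, dilation, M);
    arma::mat Y(y.begin() + (size_t)H * W * Cout * n,
                (size_t)H * W, Cout, false, true);
    Y = M * Wm;
    Y.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export(name = ".conv2dBackward")]]
List conv2dBackward(NumericVector x, NumericVector w, NumericVector dy,
                    int dilation) {
  IntegerVector xd = dims4(x);
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xd;
  NumericVector dw((size_t)k * k * C * Cout);
  dw.attr("dim") = wd;
  NumericVector db(Cout);
  arma::mat Wm(w.begin(), (size_t)k * k * C, Cout, false, true);
  arma::mat dWm(dw.begin(), (size_t)k * k * C, Cout, false, true);
  arma::vec dbv(db.begin(), Cout, false, true);
  arma::mat M((size_t)H * W, (size_t)k * k * C);
  arma::mat dM((size_t)H * W, (size_t)k * k * C);
  for (int n = 0; n < N; ++n) {
    arma::mat dY(const_cast<double*>(dy.begin()) + (size_t)H * W * Cout * n,
                 (size_t)H * W, Cout, false, true);
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, dilation, M);
    dWm += M.t() * dY;
    dM = dY * Wm.t();
    col2im(dM, H, W, C, k, dilation, dx.begin() + (size_t)H * W * C * n);
    dbv += arma::sum(dY, 0).t();
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Transposed convolution, kernel 2x2, stride 2 (learned upsampling).
// w dim: (2, 2, Cin, Cout); output (2H, 2W, Cout, N).
// [[Rcpp::export(name = ".convT2Forward")]]
NumericVector convT2Forward(NumericVector x, NumericVector w,
                            NumericVector bias) {
  IntegerVector xd = dims4(x);
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Cout = wd[3];
  const int H2 = 2 * H, W2 = 2 * W;
  NumericVector y((size_t)H2 * W2 * Cout * N);
  y.attr("dim") = IntegerVector::create(H2, W2, Cout, N);
  for (int n = 0; n < N; ++n) {
    arma::mat X(const_cast<double*>(x.begin()) + (size_t)H * W * C * n,
                (size_t)H * W, C, false, true);
    double* yo = y.begin() + (size_t)H2 * W2 * Cout * n;
    for (int a = 0; a < 2; ++a) {
      for (int b = 0; b < 2; ++b) {
        arma::mat Wab(C, Cout);
        for (int ci = 0; ci < C; ++ci)
          for (int co = 0; co < Cout; ++co)
            Wab(ci, co) = w[a + 2 * b + 4 * (ci + (size_t)C * co)];
        arma::mat Y = X * Wab;           // (H*W) x Cout
        for (int co = 0; co < Cout; ++co) {
          double* yc = yo + (size_t)H2 * W2 * co;
          const double* ycol = Y.colptr(co);
          const double bi = bias[co];
          for (int wcol = 0; wcol < W; ++wcol) {
            double* dst = yc + a + (size_t)H2 * (2 * wcol + b);
            const double* src = ycol + (size_t)H * wcol;
            for (int h = 0; h < H; ++h) dst[2 * h] = src[h] + bi;
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".convT2Backward")]]
List convT2Backward(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = dims4(x);
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Cout = wd[3];
  const int H2 = 2 * H, W2 = 2 * W;
  NumericVector dx((size_t)H * W * C * N);  dx.attr("dim") = xd;
  NumericVector dw((size_t)4 * C * Cout);   dw.attr("dim") = wd;
  NumericVector db(Cout);
  arma::mat dY((size_t)H * W, Cout);
  for (int n = 0; n < N; ++n) {
    arma::mat X(const_cast<double*>(x.begin()) + (size_t)H * W * C * n,
                (size_t)H * W, C, false, true);
    arma::mat dX(dx.begin() + (size_t)H * W * C * n,
                 (size_t)H * W, C, false, true);
    const double* dyo = dy.begin() + (size_t)H2 * W2 * Cout * n;
    for (int a = 0; a < 2; ++a) {
      for (int b = 0; b < 2; ++b) {
        for (int co = 0; co < Cout; ++co) {
          const double* dyc = dyo + (size_t)H2 * W2 * co;
          double* dcol = dY.colptr(co);
          double acc = 0.0;
          for (int wcol = 0; wcol < W; ++wcol) {
            const double* src = dyc + a + (size_t)H2 * (2 * wcol + b);
            double* dst = dcol + (size_t)H * wcol;
            for (int h = 0; h < H; ++h) { dst[h] = src[2 * h]; acc += dst[h]; }
          }
          db[co] += acc;
        }
        arma::mat Wab(C, Cout);
        for (int ci = 0; ci < C; ++ci)
          for (int co = 0; co < Cout; ++co)
            Wab(ci, co) = w[a + 2 * b + 4 * (ci + (size_t)C * co)];
        arma::mat dWab = X.t() * dY;     // C x Cout
        for (int ci = 0; ci < C; ++ci)
          for (int co = 0; co < Cout; ++co)
            dw[a + 2 * b + 4 * (ci + (size_t)C * co)] += dWab(ci, co);
        dX += dY * Wab.t();
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2; returns pooled tensor and argmax linear
// offsets (0-based within each (H,W) plane) for the backward pass.
// [[Rcpp::export(name = ".maxPool2Forward")]]
List maxPool2Forward(NumericVector x) {
  IntegerVector xd = dims4(x);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("spatial size must be even for 2x2 pooling");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  double* yp = y.begin();
  int* ip = idx.begin();
  size_t p = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          int best = 2 * ho + H * (2 * wo);
          double bv = xc[best];
          const int cand[3] = {2 * ho + 1 + H * (2 * wo),
                               2 * ho + H * (2 * wo + 1),
                               2 * ho + 1 + H * (2 * wo + 1)};
          for (int q = 0; q < 3; ++q)
            if (xc[cand[q]] > bv) { bv = xc[cand[q]]; best = cand[q]; }
          yp[p] = bv; ip[p] = best; ++p;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxPool2Backward")]]
NumericVector maxPool2Backward(NumericVector dy, IntegerVector idx,
                               IntegerVector inDim) {
  const int H = inDim[0], W = inDim[1], C = inDim[2], N = inDim[3];
  IntegerVector yd = dims4(dy);
  const int Ho = yd[0], Wo = yd[1];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* dp = dy.begin();
  const int* ip = idx.begin();
  size_t p = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* xc = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int q = 0; q < Ho * Wo; ++q, ++p) xc[ip[p]] += dp[p];
    }
  return dx;
}

// Batch normalisation, training mode: per-channel statistics over
// (H, W, N); returns the normalised output plus mu and 1/sqrt(var + eps).
// [[Rcpp::export(name = ".bnTrainForward")]]
List bnTrainForward(NumericVector x, NumericVector gamma,
                    NumericVector beta, double eps) {
  IntegerVector xd = dims4(x);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t HW = (size_t)H * W;
  const double M = (double)HW * N;
  NumericVector mu(C), invstd(C);
  NumericVector y(x.size());
  y.attr("dim") = xd;
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + HW * (c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
    }
    const double m = s / M;
    double var = s2 / M - m * m;
    if (var < 0) var = 0;
    const double is = 1.0 / std::sqrt(var + eps);
    mu[c] = m; invstd[c] = is;
    const double a = gamma[c] * is, b = beta[c] - a * m;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + HW * (c + (size_t)C * n);
      double* yc = y.begin() + HW * (c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) yc[i] = a * xc[i] + b;
    }
  }
  return List::create(_["y"] = y, _["mu"] = mu, _["invstd"] = invstd);
}

// Per-channel affine y = scale[c] * x + shift[c] (BN inference mode).
// [[Rcpp::export(name = ".chanAffine")]]
NumericVector chanAffine(NumericVector x, NumericVector scale,
                         NumericVector shift) {
  IntegerVector xd = dims4(x);
  const int C = xd[2], N = xd[3];
  const size_t HW = (size_t)xd[0] * xd[1];
  NumericVector y(x.size());
  y.attr("dim") = xd;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double a = scale[c], b = shift[c];
      const double* xc = x.begin() + HW * (c + (size_t)C * n);
      double* yc = y.begin() + HW * (c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) yc[i] = a * xc[i] + b;
    }
  return y;
}

// Batch-norm backward (training statistics), from the cached input.
// [[Rcpp::export(name = ".bnBackward")]]
List bnBackward(NumericVector x, NumericVector dy, NumericVector gamma,
                NumericVector mu, NumericVector invstd) {
  IntegerVector xd = dims4(x);
  const int C = xd[2], N = xd[3];
  const size_t HW = (size_t)xd[0] * xd[1];
  const double M = (double)HW * N;
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double m = mu[c], is = invstd[c], g = gamma[c];
    double t1 = 0, t2 = 0;   // sum(dy), sum(dy * xhat)
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + HW * (c + (size_t)C * n);
      const double* dc = dy.begin() + HW * (c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) {
        t1 += dc[i];
        t2 += dc[i] * (xc[i] - m) * is;
      }
    }
    dbeta[c] = t1; dgamma[c] = t2;
    const double c1 = g * t1 / M, c2 = g * t2 / M;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + HW * (c + (size_t)C * n);
      const double* dc = dy.begin() + HW * (c + (size_t)C * n);
      double* oc = dx.begin() + HW * (c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) {
        const double xhat = (xc[i] - m) * is;
        oc[i] = is * (g * dc[i] - c1 - xhat * c2);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export(name = ".reluForward")]]
NumericVector reluForward(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) yp[i] = xp[i] > 0 ? xp[i] : 0;
  return y;
}

// ReLU backward using the cached *output* (y > 0 iff x > 0).
// [[Rcpp::export(name = ".reluBackward")]]
NumericVector reluBackward(NumericVector y, NumericVector dy) {
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  const double* yp = y.begin();
  const double* dp = dy.begin();
  double* op = dx.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i) op[i] = yp[i] > 0 ? dp[i] : 0;
  return dx;
}

// Concatenate two (H,W,C,N) tensors along the channel axis.
// [[Rcpp::export(name = ".catChannels")]]
NumericVector catChannelsC(NumericVector a, NumericVector b) {
  IntegerVector da = dims4(a), db = dims4(b);
  const size_t HW = (size_t)da[0] * da[1];
  const int Ca = da[2], Cb = db[2], N = da[3];
  NumericVector y(HW * (Ca + Cb) * N);
  y.attr("dim") = IntegerVector::create(da[0], da[1], Ca + Cb, N);
  for (int n = 0; n < N; ++n) {
    std::copy(a.begin() + HW * Ca * n, a.begin() + HW * Ca * (n + 1),
              y.begin() + HW * (Ca + Cb) * n);
    std::copy(b.begin() + HW * Cb * n, b.begin() + HW * Cb * (n + 1),
              y.begin() + HW * (Ca + Cb) * n + HW * Ca);
  }
  return y;
}

// Split a (H,W,Ca+Cb,N) tensor back into its channel halves.
// [[Rcpp::export(name = ".splitChannels")]]
List splitChannelsC(NumericVector x, int ca) {
  IntegerVector xd = dims4(x);
  const size_t HW = (size_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3], cb = C - ca;
  NumericVector a(HW * ca * N), b(HW * cb * N);
  a.attr("dim") = IntegerVector::create(xd[0], xd[1], ca, N);
  b.attr("dim") = IntegerVector::create(xd[0], xd[1], cb, N);
  for (int n = 0; n < N; ++n) {
    std::copy(x.begin() + HW * C * n, x.begin() + HW * C * n + HW * ca,
              a.begin() + HW * ca * n);
    std::copy(x.begin() + HW * C * n + HW * ca, x.begin() + HW * C * (n + 1),
              b.begin() + HW * cb * n);
  }
  return List::create(_["a"] = a, _["b"] = b);
}

// 8-connected component labelling of a binary matrix (0 background).
// [[Rcpp::export(name = ".label8")]]
IntegerMatrix label8(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  for (int c0 = 0; c0 < W; ++c0)
    for (int r0 = 0; r0 < H; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0)) continue;
      ++next;
      stack.clear();
      stack.push_back(r0 + H * c0);
      lab(r0, c0) = next;
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int r = p % H, c = p / H;
        for (int dc = -1; dc <= 1; ++dc)
          for (int dr = -1; dr <= 1; ++dr) {
            if (!dr && !dc) continue;
            const int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
            if (mask(rr, cc) && !lab(rr, cc)) {
              lab(rr, cc) = next;
              stack.push_back(rr + H * cc);
            }
          }
      }
    }
  return lab;
}
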
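// Low-level volumetric kernels: 3D convolution (im2col + GEMM), pooling,
// upsampling, trilinear warping/resampling, connected components and
// neighbourhood filters. All deterministic; no internal RNG.
//
// Tensor layout convention (column-major R arrays):
//   feature maps: dim = c(D, H, W, C, N)   (spatial fastest, batch slowest)
//   conv weights: dim = c(K*K*K*Cin, Cout) with the kernel flattened
//                 kd fastest, then kh, kw, cin (matches im2col row order)
//   displacement fields: dim = c(D, H, W, 3) in voxel units per axis

#include <RcppArmadillo.h>
#include <queue>
using namespace Rcpp;

static inline arma::uword out_dim(int in, int k, int stride, int pad) {
  return (arma::uword)((in + 2 * pad - k) / stride + 1);
}

// allocate a zeroed NumericVector with an n-dimensional dim attribute
static NumericVector alloc_nd(std::initializer_list<int> d) {
  double n = 1;
  for (int x : d) n *= x;
  NumericVector v((R_xlen_t)n);
  IntegerVector dim((int)d.size());
  int i = 0;
  for (int x : d) dim[i++] = x;
  v.attr("dim") = dim;
  return v;
}

// Build im2col matrix (K3*Cin x M) for one batch item.
static void im2col(const double* x, int D, int H, int W, int C,
                   int k, int stride, int pad,
                   int Do, int Ho, int Wo, arma::mat& col) {
  const int M = Do * Ho * Wo;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * D * H * W;
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh)
        for (int kd = 0; kd < k; ++kd) {
          const int r = kd + k * (kh + k * (kw + k * c));
          double* crow = col.memptr() + r; // stride K3*C between columns
          const int K = (int)col.n_rows;
          for (int ow = 0; ow < Wo; ++ow) {
            const int iw = ow * stride - pad + kw;
            for (int oh = 0; oh < Ho; ++oh) {
              const int ih = oh * stride - pad + kh;
              const bool okhw = (iw >= 0 && iw < W && ih >= 0 && ih < H);
              for (int od = 0; od < Do; ++od) {
                const int id = od * stride - pad + kd;
                const int m = od + Do * (oh + Ho * ow);
                double v = 0.0;
                if (okhw && id >= 0 && id < D)
                  v = xc[id + (size_t)D * (ih + (size_t)H * iw)];
                crow[(size_t)m * K] = v;
              }
            }
          }
        }
  }
  (void)M;
}

// Scatter-add columns back to gradient image (inverse of im2col).
static void col2im(const arma::mat& col, int D, int H, int W, int C,
                   int k, int stride, int pad,
                   int Do, int Ho, int Wo, double* gx) {
  const int K = (int)col.n_rows;
  for (int c = 0; c < C; ++c) {
    double* gc = gx + (size_t)c * D * H * W;
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh)
        for (int kd = 0; kd < k; ++kd) {
          const int r = kd + k * (kh + k * (kw + k * c));
          const double* crow = col.memptr() + r;
          for (int ow = 0; ow < Wo; ++ow) {
            const int iw = ow * stride - pad + kw;
            if (iw < 0 || iw >= W) continue;
            for (int oh = 0; oh < Ho; ++oh) {
              const int ih = oh * stride - pad + kh;
              if (ih < 0 || ih >= H) continue;
              for (int od = 0; od < Do; ++od) {
                const int id = od * stride - pad + kd;
                if (id < 0 || id >= D) continue;
                const int m = od + Do * (oh + Ho * ow);
                gc[id + (size_t)D * (ih + (size_t)H * iw)] += crow[(size_t)m * K];
              }
            }
          }
        }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d(NumericVector x, NumericMatrix wmat, NumericVector b,
                         int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2], C = xd[3], N = xd[4];
  const int Do = (int)out_dim(D, k, stride, pad);
  const int Ho = (int)out_dim(H, k, stride, pad);
  const int Wo = (int)out_dim(W, k, stride, pad);
  const int Cout = wmat.ncol();
  const int K = k * k * k * C;
  if (wmat.nrow() != K) stop("weight rows do not match kernel/in-channels");
  const int M = Do * Ho * Wo;
  NumericVector y = alloc_nd({Do, Ho, Wo, Cout, N});
  arma::mat wm(wmat.begin(), K, Cout, false, true);
  arma::mat col(K, M);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * D * H * W * C, D, H, W, C, k, stride, pad,
           Do, Ho, Wo, col);
    arma::mat yt(y.begin() + (size_t)n * M * Cout, M, Cout, false, true);
    yt = col.t() * wm;
    for (int co = 0; co < Cout; ++co) yt.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, NumericMatrix wmat, NumericVector gy,
                    int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2], C = xd[3], N = xd[4];
  const int Do = (int)out_dim(D, k, stride, pad);
  const int Ho = (int)out_dim(H, k, stride, pad);
  const int Wo = (int)out_dim(W, k, stride, pad);
  const int Cout = wmat.ncol();
  const int K = k * k * k * C;
  const int M = Do * Ho * Wo;
  NumericVector gx = alloc_nd({D, H, W, C, N});
  NumericMatrix gw(K, Cout);
  NumericVector gb(Cout);
  arma::mat wm(wmat.begin(), K, Cout, false, true);
  arma::mat gwm(gw.begin(), K, Cout, false, true);
  arma::vec gbv(gb.begin(), Cout, false, true);
  arma::mat col(K, M);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * D * H * W * C, D, H, W, C, k, stride, pad,
           Do, Ho, Wo, col);
    arma::mat gyt(const_cast<double*>(gy.begin()) + (size_t)n * M * Cout,
                  M, Cout, false, true);
    gwm += col * gyt;
    gbv += arma::sum(gyt, 0).t();
    arma::mat gcol = wm * gyt.t();
    col2im(gcol, D, H, W, C, k, stride, pad, Do, Ho, Wo,
           gx.begin() + (size_t)n * D * H * W * C);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x average pooling (non-overlapping) -------------------------------------

// [[Rcpp::export]]
NumericVector cpp_avgpool2(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2], C = xd[3], N = xd[4];
  const int Do = D / 2, Ho = H / 2, Wo = W / 2;
  NumericVector y = alloc_nd({Do, Ho, Wo, C, N});
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int cn = 0; cn < C * N; ++cn) {
    const double* xs = xp + (size_t)cn * D * H * W;
    double* ys = yp + (size_t)cn * Do * Ho * Wo;
    for (int ow = 0; ow < Wo; ++ow)
      for (int oh = 0; oh < Ho; ++oh)
        for (int od = 0; od < Do; ++od) {
          double s = 0;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh)
              for (int dd = 0; dd < 2; ++dd)
                s += xs[(2 * od + dd) + (size_t)D * ((2 * oh + dh) + (size_t)H * (2 * ow + dw))];
          ys[od + (size_t)Do * (oh + (size_t)Ho * ow)] = s / 8.0;
        }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool2_bwd(NumericVector gy, IntegerVector xdim) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3], N = xdim[4];
  const int Do = D / 2, Ho = H / 2, Wo = W / 2;
  NumericVector gx = alloc_nd({D, H, W, C, N});
  const double* gp = gy.begin();
  double* xp = gx.begin();
  for (int cn = 0; cn < C * N; ++cn) {
    const double* gs = gp + (size_t)cn * Do * Ho * Wo;
    double* xs = xp + (size_t)cn * D * H * W;
    for (int ow = 0; ow < Wo; ++ow)
      for (int oh = 0; oh < Ho; ++oh)
        for (int od = 0; od < Do; ++od) {
          const double g = gs[od + (size_t)Do * (oh + (size_t)Ho * ow)] / 8.0;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh)
              for (int dd = 0; dd < 2; ++dd)
                xs[(2 * od + dd) + (size_t)D * ((2 * oh + dh) + (size_t)H * (2 * ow + dw))] = g;
        }
  }
  return gx;
}

// nearest-neighbour 2x upsampling ------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_upsample2(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2], C = xd[3], N = xd[4];
  const int Do = D * 2, Ho = H * 2, Wo = W * 2;
  NumericVector y = alloc_nd({Do, Ho, Wo, C, N});
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int cn = 0; cn < C * N; ++cn) {
    const double* xs = xp + (size_t)cn * D * H * W;
    double* ys = yp + (size_t)cn * Do * Ho * Wo;
    for (int ow = 0; ow < Wo; ++ow)
      for (int oh = 0; oh < Ho; ++oh)
        for (int od = 0; od < Do; ++od)
          ys[od + (size_t)Do * (oh + (size_t)Ho * ow)] =
            xs[od / 2 + (size_t)D * (oh / 2 + (size_t)H * (ow / 2))];
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bwd(NumericVector gy) {
  IntegerVector gd = gy.attr("dim");
  const int Do = gd[0], Ho = gd[1], Wo = gd[2], C = gd[3], N = gd[4];
  const int D = Do / 2, H = Ho / 2, W = Wo / 2;
  NumericVector gx = alloc_nd({D, H, W, C, N});
  const double* gp = gy.begin();
  double* xp = gx.begin();
  for (int cn = 0; cn < C * N; ++cn) {
    const double* gs = gp + (size_t)cn * Do * Ho * Wo;
    double* xs = xp + (size_t)cn * D * H * W;
    for (int ow = 0; ow < Wo; ++ow)
      for (int oh = 0; oh < Ho; ++oh)
        for (int od = 0; od < Do; ++od)
          xs[od / 2 + (size_t)D * (oh / 2 + (size_t)H * (ow / 2))] +=
            gs[od + (size_t)Do * (oh + (size_t)Ho * ow)];
  }
  return gx;
}

// trilinear warping by a displacement field --------------------------------

static inline double sample_tl(const double* v, int D, int H, int W,
                               double sd, double sh, double sw) {
  if (sd < -1 || sd > D || sh < -1 || sh > H || sw < -1 || sw > W) return 0.0;
  int d0 = (int)std::floor(sd), h0 = (int)std::floor(sh), w0 = (int)std::floor(sw);
  double fd = sd - d0, fh = sh - h0, fw = sw - w0;
  double acc = 0.0;
  for (int dw = 0; dw < 2; ++dw)
    for (int dh = 0; dh < 2; ++dh)
      for (int dd = 0; dd < 2; ++dd) {
        int d = d0 + dd, h = h0 + dh, w = w0 + dw;
        if (d < 0 || d >= D || h < 0 || h >= H || w < 0 || w >= W) continue;
        double wt = (dd ? fd : 1 - fd) * (dh ? fh : 1 - fh) * (dw ? fw : 1 - fw);
        acc += wt * v[d + (size_t)D * (h + (size_t)H * w)];
      }
  return acc;
}

// [[Rcpp::export]]
NumericVector cpp_warp(NumericVector vol, NumericVector disp) {
  IntegerVector vd = vol.attr("dim");
  const int D = vd[0], H = vd[1], W = vd[2];
  const size_t V = (size_t)D * H * W;
  NumericVector y(vol.length());
  y.attr("dim") = vd;
  const double* vp = vol.begin();
  const double* dp = disp.begin();
  double* yp = y.begin();
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d) {
        const size_t i = d + (size_t)D * (h + (size_t)H * w);
        yp[i] = sample_tl(vp, D, H, W, d + dp[i], h + dp[i + V], w + dp[i + 2 * V]);
      }
  return y;
}

// gradient of warp output w.r.t. the displacement field
// [[Rcpp::export]]
NumericVector cpp_warp_bwd(NumericVector vol, NumericVector disp, NumericVector gy) {
  IntegerVector vd = vol.attr("dim");
  const int D = vd[0], H = vd[1], W = vd[2];
  const size_t V = (size_t)D * H * W;
  NumericVector gd = alloc_nd({D, H, W, 3});
  const double* vp = vol.begin();
  const double* dp = disp.begin();
  const double* gp = gy.begin();
  double* op = gd.begin();
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d) {
        const size_t i = d + (size_t)D * (h + (size_t)H * w);
        const double g = gp[i];
        if (g == 0.0) continue;
        double sd = d + dp[i], sh = h + dp[i + V], sw = w + dp[i + 2 * V];
        if (sd < -1 || sd > D || sh < -1 || sh > H || sw < -1 || sw > W) continue;
        int d0 = (int)std::floor(sd), h0 = (int)std::floor(sh), w0 = (int)std::floor(sw);
        double fd = sd - d0, fh = sh - h0, fw = sw - w0;
        double ddd = 0, dhh = 0, dww = 0;
        for (int dw2 = 0; dw2 < 2; ++dw2)
          for (int dh2 = 0; dh2 < 2; ++dh2)
            for (int dd2 = 0; dd2 < 2; ++dd2) {
              int dd_ = d0 + dd2, hh_ = h0 + dh2, ww_ = w0 + dw2;
              if (dd_ < 0 || dd_ >= D || hh_ < 0 || hh_ >= H || ww_ < 0 || ww_ >= W) continue;
              double val = vp[dd_ + (size_t)D * (hh_ + (size_t)H * ww_)];
              double wd = dd2 ? fd : 1 - fd, wh = dh2 ? fh : 1 - fh, ww2 = dw2 ? fw : 1 - fw;
              ddd += (dd2 ? 1.0 : -1.0) * wh * ww2 * val;
              dhh += wd * (dh2 ? 1.0 : -1.0) * ww2 * val;
              dww += wd * wh * (dw2 ? 1.0 : -1.0) * val;
            }
        op[i] += g * ddd;
        op[i + V] += g * dhh;
        op[i + 2 * V] += g * dww;
      }
  return gd;
}

// affine resampling ---------------------------------------------------------
// mat (4x4) maps 0-based target voxel coordinates to 0-based source voxel
// coordinates; interp: 0 = nearest, 1 = trilinear. Outside source -> 0.

// [[Rcpp::export]]
NumericVector cpp_resample_affine(NumericVector vol, NumericMatrix mat,
                                  IntegerVector tdim, int interp) {
  IntegerVector vd = vol.attr("dim");
  const int D = vd[0], H = vd[1], W = vd[2];
  const int Dt = tdim[0], Ht = tdim[1], Wt = tdim[2];
  NumericVector y(Dimension(Dt, Ht, Wt));
  const double* vp = vol.begin();
  double* yp = y.begin();
  const double m00 = mat(0,0), m01 = mat(0,1), m02 = mat(0,2), m03 = mat(0,3);
  const double m10 = mat(1,0), m11 = mat(1,1), m12 = mat(1,2), m13 = mat(1,3);
  const double m20 = mat(2,0), m21 = mat(2,1), m22 = mat(2,2), m23 = mat(2,3);
  for (int w = 0; w < Wt; ++w)
    for (int h = 0; h < Ht; ++h)
      for (int d = 0; d < Dt; ++d) {
        const double sd = m00 * d + m01 * h + m02 * w + m03;
        const double sh = m10 * d + m11 * h + m12 * w + m13;
        const double sw = m20 * d + m21 * h + m22 * w + m23;
        double val;
        if (interp == 0) {
          int id = (int)std::lround(sd), ih = (int)std::lround(sh), iw = (int)std::lround(sw);
          val = (id >= 0 && id < D && ih >= 0 && ih < H && iw >= 0 && iw < W)
            ? vp[id + (size_t)D * (ih + (size_t)H * iw)] : 0.0;
        } else {
          val = sample_tl(vp, D, H, W, sd, sh, sw);
        }
        yp[d + (size_t)Dt * (h + (size_t)Ht * w)] = val;
      }
  return y;
}

// trilinear resize with edge clamping (for smooth coarse fields, pyramids)
// [[Rcpp::export]]
NumericVector cpp_trilinear_resize(NumericVector vol, IntegerVector tdim) {
  IntegerVector vd = vol.attr("dim");
  const int D = vd[0], H = vd[1], W = vd[2];
  const int Dt = tdim[0], Ht = tdim[1], Wt = tdim[2];
  NumericVector y(Dimension(Dt, Ht, Wt));
  const double* vp = vol.begin();
  double* yp = y.begin();
  const double sx = (double)D / Dt, sy = (double)H / Ht, sz = (double)W / Wt;
  for (int w = 0; w < Wt; ++w)
    for (int h = 0; h < Ht; ++h)
      for (int d = 0; d < Dt; ++d) {
        double sd = (d + 0.5) * sx - 0.5, sh = (h + 0.5) * sy - 0.5, sw = (w + 0.5) * sz - 0.5;
        sd = std::min(std::max(sd, 0.0), (double)D - 1);
        sh = std::min(std::max(sh, 0.0), (double)H - 1);
        sw = std::min(std::max(sw, 0.0), (double)W - 1);
        yp[d + (size_t)Dt * (h + (size_t)Ht * w)] = sample_tl(vp, D, H, W, sd, sh, sw);
      }
  return y;
}

// block-mean downsampling by integer factor (registration pyramid)
// [[Rcpp::export]]
NumericVector cpp_block_mean(NumericVector vol, int f) {
  IntegerVector vd = vol.attr("dim");
  const int D = vd[0], H = vd[1], W = vd[2];
  const int Do = D / f, Ho = H / f, Wo = W / f;
  NumericVector y(Dimension(Do, Ho, Wo));
  const double* vp = vol.begin();
  double* yp = y.begin();
  const double inv = 1.0 / (f * f * f);
  for (int ow = 0; ow < Wo; ++ow)
    for (int oh = 0; oh < Ho; ++oh)
      for (int od = 0; od < Do; ++od) {
        double s = 0;
        for (int dw = 0; dw < f; ++dw)
          for (int dh = 0; dh < f; ++dh)
            for (int dd = 0; dd < f; ++dd)
              s += vp[(f * od + dd) + (size_t)D * ((f * oh + dh) + (size_t)H * (f * ow + dw))];
        yp[od + (size_t)Do * (oh + (size_t)Ho * ow)] = s * inv;
      }
  return y;
}

// connected components ------------------------------------------------------
// BFS labelling of a binary volume; connectivity 6 or 26. Labels 1..K in
// deterministic scan order.

// [[Rcpp::export]]
IntegerVector cpp_label_components(NumericVector mask, int connectivity) {
  IntegerVector md = mask.attr("dim");
  const int D = md[0], H = md[1], W = md[2];
  const size_t V = (size_t)D * H * W;
  IntegerVector lab(mask.length());
  lab.attr("dim") = md;
  const double* mp = mask.begin();
  int* lp = lab.begin();
  std::vector<std::array<int,3>> offs;
  for (int dw = -1; dw <= 1; ++dw)
    for (int dh = -1; dh <= 1; ++dh)
      for (int dd = -1; dd <= 1; ++dd) {
        if (dd == 0 && dh == 0 && dw == 0) continue;
        int manh = std::abs(dd) + std::abs(dh) + std::abs(dw);
        if (connectivity == 6 && manh > 1) continue;
        offs.push_back({dd, dh, dw});
      }
  int next = 0;
  std::vector<size_t> stack;
  for (size_t i = 0; i < V; ++i) {
    if (mp[i] == 0.0 || lp[i] != 0) continue;
    ++next;
    stack.clear();
    stack.push_back(i);
    lp[i] = next;
    while (!stack.empty()) {
      size_t j = stack.back(); stack.pop_back();
      int d = (int)(j % D), rem = (int)(j / D);
      int h = rem % H, w = rem / H;
      for (auto& o : offs) {
        int nd = d + o[0], nh = h + o[1], nw = w + o[2];
        if (nd < 0 || nd >= D || nh < 0 || nh >= H || nw < 0 || nw >= W) continue;
        size_t nj = nd + (size_t)D * (nh + (size_t)H * nw);
        if (mp[nj] != 0.0 && lp[nj] == 0) { lp[nj] = next; stack.push_back(nj); }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// mode filter of an integer label map within a mask (26-neighbourhood incl.
// centre); ties resolved toward the smallest label. labels >= 0 in mask.

// [[Rcpp::export]]
IntegerVector cpp_mode_filter(IntegerVector labels, NumericVector mask,
                              int iters, int n_labels) {
  IntegerVector ld = labels.attr("dim");
  const int D = ld[0], H = ld[1], W = ld[2];
  IntegerVector cur = clone(labels);
  IntegerVector nxt = clone(labels);
  const double* mp = mask.begin();
  std::vector<int> cnt(n_labels);
  for (int it = 0; it < iters; ++it) {
    const int* cp = cur.begin();
    int* np = nxt.begin();
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h)
        for (int d = 0; d < D; ++d) {
          const size_t i = d + (size_t)D * (h + (size_t)H * w);
          if (mp[i] == 0.0) { np[i] = cp[i]; continue; }
          std::fill(cnt.begin(), cnt.end(), 0);
          for (int dw = -1; dw <= 1; ++dw)
            for (int dh = -1; dh <= 1; ++dh)
              for (int dd = -1; dd <= 1; ++dd) {
                int nd = d + dd, nh = h + dh, nw = w + dw;
                if (nd < 0 || nd >= D || nh < 0 || nh >= H || nw < 0 || nw >= W) continue;
                size_t nj = nd + (size_t)D * (nh + (size_t)H * nw);
                if (mp[nj] == 0.0) continue;
                int l = cp[nj];
                if (l >= 0 && l < n_labels) ++cnt[l];
              }
          int best = cp[i], bc = -1;
          for (int l = 0; l < n_labels; ++l)
            if (cnt[l] > bc) { bc = cnt[l]; best = l; }
          np[i] = best;
        }
    std::swap(cur, nxt);
  }
  cur.attr("dim") = ld;
  return cur;
}

// 3x3x3 min/max filter (binary morphology building block)
// [[Rcpp::export]]
NumericVector cpp_minmax_filter(NumericVector x, bool take_max) {
  IntegerVector xd = x.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2];
  NumericVector y(x.length());
  y.attr("dim") = xd;
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d) {
        double acc = take_max ? -1e300 : 1e300;
        for (int dw = -1; dw <= 1; ++dw)
          for (int dh = -1; dh <= 1; ++dh)
            for (int dd = -1; dd <= 1; ++dd) {
              int nd = d + dd, nh = h + dh, nw = w + dw;
              double v = 0.0; // outside treated as background
              if (nd >= 0 && nd < D && nh >= 0 && nh < H && nw >= 0 && nw < W)
                v = xp[nd + (size_t)D * (nh + (size_t)H * nw)];
              acc = take_max ? std::max(acc, v) : std::min(acc, v);
            }
        yp[d + (size_t)D * (h + (size_t)H * w)] = acc;
      }
  return y;
}
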
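// Low-level numeric kernels: 3D convolution (im2col + GEMM) with gradients,
// depthwise 3D convolution, 3D max pooling, trilinear resampling, and 2D
// connected-component labeling.
//
// Tensor layout everywhere: R arrays in column-major order with
//   activations dim (D, H, W, C, N)  -> index d + D*(h + H*(w + W*(c + C*n)))
//   conv weights dim (kd, kh, kw, Cin, Cout)
// so a weight array flattens to a (K x Cout) matrix with K = kd*kh*kw*Cin and
// the im2col patch matrix uses the identical row ordering.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct ConvGeom {
  int D, H, W, C, N;          // input
  int kd, kh, kw, Cout;       // kernel
  int sd, sh, sw;             // stride
  int pd, ph, pw;             // padding
  int Do, Ho, Wo;             // output spatial
  int K, M;                   // im2col rows, cols
};

ConvGeom conv_geom(const IntegerVector& xdim, const IntegerVector& wdim,
                   const IntegerVector& stride, const IntegerVector& pad) {
  ConvGeom g;
  g.D = xdim[0]; g.H = xdim[1]; g.W = xdim[2]; g.C = xdim[3]; g.N = xdim[4];
  g.kd = wdim[0]; g.kh = wdim[1]; g.kw = wdim[2]; g.Cout = wdim[4];
  if (wdim[3] != g.C) stop("conv3d: channel mismatch");
  g.sd = stride[0]; g.sh = stride[1]; g.sw = stride[2];
  g.pd = pad[0]; g.ph = pad[1]; g.pw = pad[2];
  g.Do = (g.D + 2 * g.pd - g.kd) / g.sd + 1;
  g.Ho = (g.H + 2 * g.ph - g.kh) / g.sh + 1;
  g.Wo = (g.W + 2 * g.pw - g.kw) / g.sw + 1;
  if (g.Do < 1 || g.Ho < 1 || g.Wo < 1) stop("input too small");
  g.K = g.kd * g.kh * g.kw * g.C;
  g.M = g.Do * g.Ho * g.Wo;
  return g;
}

// Fill the im2col matrix (K x M) for sample n.
void im2col(const double* x, const ConvGeom& g, int n, arma::mat& col) {
  const long sampOff = (long)g.D * g.H * g.W * g.C * n;
  col.zeros();
  for (int ow = 0; ow < g.Wo; ++ow) {
    for (int oh = 0; oh < g.Ho; ++oh) {
      for (int od = 0; od < g.Do; ++od) {
        const int m = od + g.Do * (oh + g.Ho * ow);
        double* cm = col.colptr(m);
        for (int c = 0; c < g.C; ++c) {
          for (int dw = 0; dw < g.kw; ++dw) {
            const int iw = ow * g.sw - g.pw + dw;
            if (iw < 0 || iw >= g.W) continue;
            for (int dh = 0; dh < g.kh; ++dh) {
              const int ih = oh * g.sh - g.ph + dh;
              if (ih < 0 || ih >= g.H) continue;
              for (int dd = 0; dd < g.kd; ++dd) {
                const int id = od * g.sd - g.pd + dd;
                if (id < 0 || id >= g.D) continue;
                const long xi = sampOff + id + (long)g.D * (ih + (long)g.H * (iw + (long)g.W * c));
                const int r = dd + g.kd * (dh + g.kh * (dw + g.kw * c));
                cm[r] = x[xi];
              }
            }
          }
        }
      }
    }
  }
}

// Scatter-add a dcol matrix (K x M) back into dx for sample n.
void col2im_add(double* dx, const ConvGeom& g, int n, const arma::mat& dcol) {
  const long sampOff = (long)g.D * g.H * g.W * g.C * n;
  for (int ow = 0; ow < g.Wo; ++ow) {
    for (int oh = 0; oh < g.Ho; ++oh) {
      for (int od = 0; od < g.Do; ++od) {
        const int m = od + g.Do * (oh + g.Ho * ow);
        const double* cm = dcol.colptr(m);
        for (int c = 0; c < g.C; ++c) {
          for (int dw = 0; dw < g.kw; ++dw) {
            const int iw = ow * g.sw - g.pw + dw;
            if (iw < 0 || iw >= g.W) continue;
            for (int dh = 0; dh < g.kh; ++dh) {
              const int ih = oh * g.sh - g.ph + dh;
              if (ih < 0 || ih >= g.H) continue;
              for (int dd = 0; dd < g.kd; ++dd) {
                const int id = od * g.sd - g.pd + dd;
                if (id < 0 || id >= g.D) continue;
                const long xi = sampOff + id + (long)g.D * (ih + (long)g.H * (iw + (long)g.W * c));
                const int r = dd + g.kd * (dh + g.kh * (dw + g.kw * c));
                dx[xi] += cm[r];
              }
            }
          }
        }
      }
    }
  }
}

} // namespace

// [[Rcpp::export(name = ".conv3d_fwd")]]
NumericVector conv3d_fwd(NumericVector x, NumericVector w, NumericVector bias,
                         IntegerVector stride, IntegerVector pad) {
  IntegerVector xdim = x.attr("dim"), wdim = w.attr("dim");
  ConvGeom g = conv_geom(xdim, wdim, stride, pad);
  NumericVector y((long)g.M * g.Cout * g.N);
  arma::mat Wm(w.begin(), g.K, g.Cout, false, true);
  arma::mat col(g.K, g.M);
  for (int n = 0; n < g.N; ++n) {
    im2col(x.begin(), g, n, col);
    arma::mat yn(y.begin() + (long)g.M * g.Cout * n, g.M, g.Cout, false, true);
    yn = col.t() * Wm;
    yn.each_row() += arma::rowvec(bias.begin(), g.Cout);
  }
  y.attr("dim") = IntegerVector::create(g.Do, g.Ho, g.Wo, g.Cout, g.N);
  return y;
}

// [[Rcpp::export(name = ".conv3d_bwd")]]
List conv3d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                IntegerVector stride, IntegerVector pad) {
  IntegerVector xdim = x.attr("dim"), wdim = w.attr("dim");
  ConvGeom g = conv_geom(xdim, wdim, stride, pad);
  NumericVector dx((long)x.size());
  NumericVector dw((long)w.size());
  NumericVector db(g.Cout);
  arma::mat Wm(w.begin(), g.K, g.Cout, false, true);
  arma::mat dWm(dw.begin(), g.K, g.Cout, false, true);
  arma::vec dbv(db.begin(), g.Cout, false, true);
  arma::mat col(g.K, g.M);
  for (int n = 0; n < g.N; ++n) {
    arma::mat dyn(dy.begin() + (long)g.M * g.Cout * n, g.M, g.Cout, false, true);
    im2col(x.begin(), g, n, col);
    dWm += col * dyn;
    dbv += arma::sum(dyn, 0).t();
    arma::mat dcol = Wm * dyn.t();
    col2im_add(dx.begin(), g, n, dcol);
  }
  dx.attr("dim") = xdim;
  dw.attr("dim") = wdim;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Depthwise 3D convolution: weights dim (kd, kh, kw, 1, C); channel c of the
// output sees only channel c of the input.
// [[Rcpp::export(name = ".dwconv3d_fwd")]]
NumericVector dwconv3d_fwd(NumericVector x, NumericVector w, NumericVector bias,
                           IntegerVector stride, IntegerVector pad) {
  IntegerVector xdim = x.attr("dim"), wdim = w.attr("dim");
  int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3], N = xdim[4];
  int kd = wdim[0], kh = wdim[1], kw = wdim[2];
  if (wdim[4] != C) stop("dwconv3d: channel mismatch");
  int sd = stride[0], sh = stride[1], sw = stride[2];
  int pd = pad[0], ph = pad[1], pw = pad[2];
  int Do = (D + 2 * pd - kd) / sd + 1;
  int Ho = (H + 2 * ph - kh) / sh + 1;
  int Wo = (W + 2 * pw - kw) / sw + 1;
  if (Do < 1 || Ho < 1 || Wo < 1) stop("input too small");
  NumericVector y((long)Do * Ho * Wo * C * N);
  const double* xp = x.begin();
  double* yp = y.begin();
  const double* wp = w.begin();
  const int klen = kd * kh * kw;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const long xo = (long)D * H * W * (c + (long)C * n);
      const long yo = (long)Do * Ho * Wo * (c + (long)C * n);
      const double* wc = wp + (long)klen * c;
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh)
          for (int od = 0; od < Do; ++od) {
            double acc = bias[c];
            for (int dw_ = 0; dw_ < kw; ++dw_) {
              int iw = ow * sw - pw + dw_;
              if (iw < 0 || iw >= W) continue;
              for (int dh = 0; dh < kh; ++dh) {
                int ih = oh * sh - ph + dh;
                if (ih < 0 || ih >= H) continue;
                for (int dd = 0; dd < kd; ++dd) {
                  int id = od * sd - pd + dd;
                  if (id < 0 || id >= D) continue;
                  acc += xp[xo + id + (long)D * (ih + (long)H * iw)] *
                         wc[dd + kd * (dh + kh * dw_)];
                }
              }
            }
            yp[yo + od + (long)Do * (oh + (long)Ho * ow)] = acc;
          }
    }
  }
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo, C, N);
  return y;
}

// [[Rcpp::export(name = ".dwconv3d_bwd")]]
List dwconv3d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                  IntegerVector stride, IntegerVector pad) {
  IntegerVector xdim = x.attr("dim"), wdim = w.attr("dim");
  int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3], N = xdim[4];
  int kd = wdim[0], kh = wdim[1], kw = wdim[2];
  int sd = stride[0], sh = stride[1], sw = stride[2];
  int pd = pad[0], ph = pad[1], pw = pad[2];
  int Do = (D + 2 * pd - kd) / sd + 1;
  int Ho = (H + 2 * ph - kh) / sh + 1;
  int Wo = (W + 2 * pw - kw) / sw + 1;
  NumericVector dx((long)x.size()), dw((long)w.size()), db(C);
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  double* dwp = dw.begin();
  const int klen = kd * kh * kw;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const long xo = (long)D * H * W * (c + (long)C * n);
      const long yo = (long)Do * Ho * Wo * (c + (long)C * n);
      const double* wc = wp + (long)klen * c;
      double* dwc = dwp + (long)klen * c;
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh)
          for (int od = 0; od < Do; ++od) {
            const double g = dyp[yo + od + (long)Do * (oh + (long)Ho * ow)];
            db[c] += g;
            for (int dw_ = 0; dw_ < kw; ++dw_) {
              int iw = ow * sw - pw + dw_;
              if (iw < 0 || iw >= W) continue;
              for (int dh = 0; dh < kh; ++dh) {
                int ih = oh * sh - ph + dh;
                if (ih < 0 || ih >= H) continue;
                for (int dd = 0; dd < kd; ++dd) {
                  int id = od * sd - pd + dd;
                  if (id < 0 || id >= D) continue;
                  const long xi = xo + id + (long)D * (ih + (long)H * iw);
                  const int wi = dd + kd * (dh + kh * dw_);
                  dwc[wi] += g * xp[xi];
                  dxp[xi] += g * wc[wi];
                }
              }
            }
          }
    }
  }
  dx.attr("dim") = xdim;
  dw.attr("dim") = wdim;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export(name = ".maxpool3d_fwd")]]
List maxpool3d_fwd(NumericVector x, IntegerVector kern, IntegerVector stride,
                   IntegerVector pad) {
  IntegerVector xdim = x.attr("dim");
  int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3], N = xdim[4];
  int kd = kern[0], kh = kern[1], kw = kern[2];
  int sd = stride[0], sh = stride[1], sw = stride[2];
  int pd = pad[0], ph = pad[1], pw = pad[2];
  int Do = (D + 2 * pd - kd) / sd + 1;
  int Ho = (H + 2 * ph - kh) / sh + 1;
  int Wo = (W + 2 * pw - kw) / sw + 1;
  if (Do < 1 || Ho < 1 || Wo < 1) stop("input too small");
  NumericVector y((long)Do * Ho * Wo * C * N);
  IntegerVector arg((long)Do * Ho * Wo * C * N);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ap = arg.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const long xo = (long)D * H * W * (c + (long)C * n);
      const long yo = (long)Do * Ho * Wo * (c + (long)C * n);
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh)
          for (int od = 0; od < Do; ++od) {
            double best = -std::numeric_limits<double>::infinity();
            long bestIdx = -1;
            for (int dw_ = 0; dw_ < kw; ++dw_) {
              int iw = ow * sw - pw + dw_;
              if (iw < 0 || iw >= W) continue;
              for (int dh = 0; dh < kh; ++dh) {
                int ih = oh * sh - ph + dh;
                if (ih < 0 || ih >= H) continue;
                for (int dd = 0; dd < kd; ++dd) {
                  int id = od * sd - pd + dd;
                  if (id < 0 || id >= D) continue;
                  long xi = xo + id + (long)D * (ih + (long)H * iw);
                  if (xp[xi] > best) { best = xp[xi]; bestIdx = xi; }
                }
              }
            }
            long m = yo + od + (long)Do * (oh + (long)Ho * ow);
            yp[m] = best;
            ap[m] = (int)bestIdx;   // fits: tensors here stay < 2^31 elements
          }
    }
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo, C, N);
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".maxpool3d_bwd")]]
NumericVector maxpool3d_bwd(NumericVector dy, IntegerVector argmax,
                            IntegerVector xdim) {
  long n = 1;
  for (int i = 0; i < xdim.size(); ++i) n *= xdim[i];
  NumericVector dx(n);
  double* dxp = dx.begin();
  const double* dyp = dy.begin();
  const int* ap = argmax.begin();
  for (long i = 0; i < (long)dy.size(); ++i)
    if (ap[i] >= 0) dxp[ap[i]] += dyp[i];
  dx.attr("dim") = xdim;
  return dx;
}

// Trilinear resampling of a (D,H,W) volume onto a new grid. Grids share the
// physical position of voxel centre (0,0,0); output voxel i maps to input
// coordinate i * step where step = out_spacing / in_spacing, clamped to the
// input domain (edge replication).
// [[Rcpp::export(name = ".resample_trilinear")]]
NumericVector resample_trilinear(NumericVector v, IntegerVector outdim,
                                 NumericVector step) {
  IntegerVector xdim = v.attr("dim");
  int D = xdim[0], H = xdim[1], W = xdim[2];
  int Do = outdim[0], Ho = outdim[1], Wo = outdim[2];
  NumericVector out((long)Do * Ho * Wo);
  const double* vp = v.begin();
  double* op = out.begin();
  for (int ow = 0; ow < Wo; ++ow) {
    double uw = std::min(std::max(ow * step[2], 0.0), (double)(W - 1));
    int w0 = (int)std::floor(uw); int w1 = std::min(w0 + 1, W - 1);
    double fw = uw - w0;
    for (int oh = 0; oh < Ho; ++oh) {
      double uh = std::min(std::max(oh * step[1], 0.0), (double)(H - 1));
      int h0 = (int)std::floor(uh); int h1 = std::min(h0 + 1, H - 1);
      double fh = uh - h0;
      for (int od = 0; od < Do; ++od) {
        double ud = std::min(std::max(od * step[0], 0.0), (double)(D - 1));
        int d0 = (int)std::floor(ud); int d1 = std::min(d0 + 1, D - 1);
        double fd = ud - d0;
        auto at = [&](int d, int h, int w) {
          return vp[d + (long)D * (h + (long)H * w)];
        };
        double c00 = at(d0, h0, w0) * (1 - fd) + at(d1, h0, w0) * fd;
        double c10 = at(d0, h1, w0) * (1 - fd) + at(d1, h1, w0) * fd;
        double c01 = at(d0, h0, w1) * (1 - fd) + at(d1, h0, w1) * fd;
        double c11 = at(d0, h1, w1) * (1 - fd) + at(d1, h1, w1) * fd;
        double c0 = c00 * (1 - fh) + c10 * fh;
        double c1 = c01 * (1 - fh) + c11 * fh;
        op[od + (long)Do * (oh + (long)Ho * ow)] = c0 * (1 - fw) + c1 * fw;
      }
    }
  }
  out.attr("dim") = outdim;
  return out;
}

// Connected-component labeling of a binary matrix, 4- or 8-connectivity.
// Components are numbered 1..k in order of first (column-major) encounter.
// [[Rcpp::export(name = ".label_components_2d")]]
IntegerMatrix label_components_2d(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<std::pair<int, int>> nbr;
  nbr.push_back({-1, 0}); nbr.push_back({1, 0});
  nbr.push_back({0, -1}); nbr.push_back({0, 1});
  if (connectivity == 8) {
    nbr.push_back({-1, -1}); nbr.push_back({-1, 1});
    nbr.push_back({1, -1});  nbr.push_back({1, 1});
  } else if (connectivity != 4) {
    stop("connectivity must be 4 or 8");
  }
  int next = 0;
  std::vector<std::pair<int, int>> stack;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back({i, j});
      lab(i, j) = next;
      while (!stack.empty()) {
        auto p = stack.back();
        stack.pop_back();
        for (auto& d : nbr) {
          int ii = p.first + d.first, jj = p.second + d.second;
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (mask(ii, jj) && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            stack.push_back({ii, jj});
          }
        }
      }
    }
  return lab;
}
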
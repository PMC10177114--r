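// Core dense kernels for the detector: same-padded strided 2-D convolution
// (forward and backward via im2col + GEMM) and an inverse-mapped bilinear
// affine sampler used for resizing, rotation and face normalization.
//
// Image/feature tensors are R arrays [H, W, C] (row index fastest), which map
// directly onto arma::cube(H, W, C). Convolution weights are R arrays
// [kh, kw, Cin, Cout]. Padding follows the "same with ceil(H/stride) output"
// convention: total pad = max((out-1)*stride + k - in, 0), split with the
// smaller half at the top/left.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

struct PadSpec {
  int out, pad_lo;
};

PadSpec same_ceil(int in, int k, int stride) {
  PadSpec p;
  p.out = (in + stride - 1) / stride;
  int total = std::max((p.out - 1) * stride + k - in, 0);
  p.pad_lo = total / 2;
  return p;
}

// im2col: rows ordered ky fastest, then kx, then ci (matches R flattening of
// a [kh, kw, Cin, Cout] weight array); columns ordered oy fastest, then ox.
arma::mat im2col(const arma::cube& x, int kh, int kw, int stride,
                 const PadSpec& ph, const PadSpec& pw) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int oh = ph.out, ow = pw.out;
  arma::mat cols(kh * kw * C, oh * ow, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    for (int kx = 0; kx < kw; ++kx) {
      for (int ky = 0; ky < kh; ++ky) {
        const int r = ky + kh * (kx + kw * ci);
        for (int ox = 0; ox < ow; ++ox) {
          const int xin = ox * stride + kx - pw.pad_lo;
          if (xin < 0 || xin >= W) continue;
          for (int oy = 0; oy < oh; ++oy) {
            const int yin = oy * stride + ky - ph.pad_lo;
            if (yin < 0 || yin >= H) continue;
            cols(r, oy + oh * ox) = x(yin, xin, ci);
          }
        }
      }
    }
  }
  return cols;
}

void col2im_acc(arma::cube& dx, const arma::mat& dcols, int kh, int kw,
                int stride, const PadSpec& ph, const PadSpec& pw) {
  const int H = dx.n_rows, W = dx.n_cols, C = dx.n_slices;
  const int oh = ph.out, ow = pw.out;
  for (int ci = 0; ci < C; ++ci) {
    for (int kx = 0; kx < kw; ++kx) {
      for (int ky = 0; ky < kh; ++ky) {
        const int r = ky + kh * (kx + kw * ci);
        for (int ox = 0; ox < ow; ++ox) {
          const int xin = ox * stride + kx - pw.pad_lo;
          if (xin < 0 || xin >= W) continue;
          for (int oy = 0; oy < oh; ++oy) {
            const int yin = oy * stride + ky - ph.pad_lo;
            if (yin < 0 || yin >= H) continue;
            dx(yin, xin, ci) += dcols(r, oy + oh * ox);
          }
        }
      }
    }
  }
}

arma::mat weight_mat(const NumericVector& w, int& kh, int& kw, int& cin,
                     int& cout) {
  IntegerVector d = w.attr("dim");
  if (d.size() != 4) stop("conv weights must be a [kh, kw, cin, cout] array");
  kh = d[0]; kw = d[1]; cin = d[2]; cout = d[3];
  return arma::mat(const_cast<double*>(w.begin()), kh * kw * cin, cout, false);
}

}  // namespace

// [[Rcpp::export(name = ".cpp_conv2d_fw")]]
arma::cube cpp_conv2d_fw(const arma::cube& x, const NumericVector& w,
                         const arma::vec& bias, int stride) {
  int kh, kw, cin, cout;
  arma::mat wm = weight_mat(w, kh, kw, cin, cout);
  if ((int)x.n_slices != cin) stop("input channel mismatch");
  PadSpec ph = same_ceil(x.n_rows, kh, stride);
  PadSpec pw = same_ceil(x.n_cols, kw, stride);
  arma::mat cols = im2col(x, kh, kw, stride, ph, pw);
  arma::mat out = wm.t() * cols;       // (cout, oh*ow)
  out.each_col() += bias;
  arma::cube y(ph.out, pw.out, cout);
  for (int co = 0; co < cout; ++co)
    y.slice(co) = arma::reshape(out.row(co).t(), ph.out, pw.out);
  return y;
}

// Forward pass that also hands back the im2col patch matrix so the
// backward pass can reuse it instead of rebuilding it.
// [[Rcpp::export(name = ".cpp_conv2d_fw_cache")]]
List cpp_conv2d_fw_cache(const arma::cube& x, const NumericVector& w,
                         const arma::vec& bias, int stride) {
  int kh, kw, cin, cout;
  arma::mat wm = weight_mat(w, kh, kw, cin, cout);
  if ((int)x.n_slices != cin) stop("input channel mismatch");
  PadSpec ph = same_ceil(x.n_rows, kh, stride);
  PadSpec pw = same_ceil(x.n_cols, kw, stride);
  arma::mat cols = im2col(x, kh, kw, stride, ph, pw);
  arma::mat out = wm.t() * cols;
  out.each_col() += bias;
  arma::cube y(ph.out, pw.out, cout);
  for (int co = 0; co < cout; ++co)
    y.slice(co) = arma::reshape(out.row(co).t(), ph.out, pw.out);
  return List::create(_["y"] = y, _["cols"] = cols);
}

// Backward pass from a cached im2col matrix; dx is skipped when need_dx is
// false (the input layer).
// [[Rcpp::export(name = ".cpp_conv2d_bw_cache")]]
List cpp_conv2d_bw_cache(const arma::mat& cols, const NumericVector& w,
                         int in_h, int in_w, int stride,
                         const arma::cube& dy, bool need_dx) {
  int kh, kw, cin, cout;
  arma::mat wm = weight_mat(w, kh, kw, cin, cout);
  PadSpec ph = same_ceil(in_h, kh, stride);
  PadSpec pw = same_ceil(in_w, kw, stride);
  const int oh = ph.out, ow = pw.out;
  arma::mat dyM(oh * ow, cout);
  for (int co = 0; co < cout; ++co)
    dyM.col(co) = arma::vectorise(dy.slice(co));
  arma::mat dwm = cols * dyM;
  arma::vec db = arma::sum(dyM, 0).t();
  NumericVector dw(dwm.begin(), dwm.end());
  dw.attr("dim") = IntegerVector::create(kh, kw, cin, cout);
  if (!need_dx) return List::create(_["dw"] = dw, _["db"] = db);
  arma::mat dcols = wm * dyM.t();
  arma::cube dx(in_h, in_w, cin, arma::fill::zeros);
  col2im_acc(dx, dcols, kh, kw, stride, ph, pw);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export(name = ".cpp_conv2d_bw")]]
List cpp_conv2d_bw(const arma::cube& x, const NumericVector& w, int stride,
                   const arma::cube& dy) {
  int kh, kw, cin, cout;
  arma::mat wm = weight_mat(w, kh, kw, cin, cout);
  PadSpec ph = same_ceil(x.n_rows, kh, stride);
  PadSpec pw = same_ceil(x.n_cols, kw, stride);
  const int oh = ph.out, ow = pw.out;
  arma::mat dyM(oh * ow, cout);
  for (int co = 0; co < cout; ++co)
    dyM.col(co) = arma::vectorise(dy.slice(co));
  arma::mat cols = im2col(x, kh, kw, stride, ph, pw);
  arma::mat dwm = cols * dyM;                     // (kh*kw*cin, cout)
  arma::vec db = arma::sum(dyM, 0).t();
  arma::mat dcols = wm * dyM.t();                 // (kh*kw*cin, oh*ow)
  arma::cube dx(x.n_rows, x.n_cols, x.n_slices, arma::fill::zeros);
  col2im_acc(dx, dcols, kh, kw, stride, ph, pw);
  NumericVector dw(dwm.begin(), dwm.end());
  dw.attr("dim") = IntegerVector::create(kh, kw, cin, cout);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Bilinear sampling under an affine map. m is a 2x3 matrix sending output
// pixel-center coordinates (x, y, 1) (origin top-left, x right, y down,
// centers at integer+0.5) to source coordinates; pixels sampled outside the
// source are zero (pad value).
// [[Rcpp::export(name = ".cpp_affine_sample")]]
arma::cube cpp_affine_sample(const arma::cube& img, const arma::mat& m,
                             int out_h, int out_w) {
  if (m.n_rows != 2 || m.n_cols != 3) stop("affine map must be 2x3");
  const int H = img.n_rows, W = img.n_cols, C = img.n_slices;
  arma::cube out(out_h, out_w, C, arma::fill::zeros);
  for (int ox = 0; ox < out_w; ++ox) {
    const double px = ox + 0.5;
    for (int oy = 0; oy < out_h; ++oy) {
      const double py = oy + 0.5;
      const double qx = m(0, 0) * px + m(0, 1) * py + m(0, 2);
      const double qy = m(1, 0) * px + m(1, 1) * py + m(1, 2);
      // fractional pixel-index coordinates
      const double fx = qx - 0.5, fy = qy - 0.5;
      const int x0 = (int)std::floor(fx), y0 = (int)std::floor(fy);
      const double ax = fx - x0, ay = fy - y0;
      for (int c = 0; c < C; ++c) {
        double v = 0.0;
        for (int dx = 0; dx <= 1; ++dx) {
          const int xs = x0 + dx;
          if (xs < 0 || xs >= W) continue;
          const double wx = dx ? ax : 1.0 - ax;
          for (int dy = 0; dy <= 1; ++dy) {
            const int ys = y0 + dy;
            if (ys < 0 || ys >= H) continue;
            const double wy = dy ? ay : 1.0 - ay;
            v += wx * wy * img(ys, xs, c);
          }
        }
        out(oy, ox, c) = v;
      }
    }
  }
  return out;
}

// Fused batch-normalization + ReLU over an [H, W, C] cube with per-image
// spatial statistics. Returns everything the backward pass needs.
// [[Rcpp::export(name = ".cpp_bn_relu_fw")]]
List cpp_bn_relu_fw(const arma::cube& x, const arma::vec& gamma,
                    const arma::vec& beta, double eps, bool train,
                    const arma::vec& run_mean, const arma::vec& run_var) {
  const int hw = x.n_rows * x.n_cols, C = x.n_slices;
  arma::mat X(const_cast<double*>(x.memptr()), hw, C, false);
  arma::rowvec mu, va;
  if (train) {
    mu = arma::mean(X, 0);
    va = arma::mean(arma::square(X), 0) - arma::square(mu);
  } else {
    mu = run_mean.t();
    va = run_var.t();
  }
  arma::rowvec inv_sd = 1.0 / arma::sqrt(va + eps);
  arma::mat xhat = X;
  xhat.each_row() -= mu;
  xhat.each_row() %= inv_sd;
  arma::mat Y = xhat;
  Y.each_row() %= gamma.t();
  Y.each_row() += beta.t();
  Y.for_each([](double& v) { if (v < 0) v = 0; });
  arma::cube y(Y.memptr(), x.n_rows, x.n_cols, C);
  return List::create(_["y"] = y, _["xhat"] = xhat,
                      _["inv_sd"] = inv_sd.t(), _["mu"] = mu.t(),
                      _["var"] = va.t());
}

// [[Rcpp::export(name = ".cpp_bn_relu_bw")]]
List cpp_bn_relu_bw(const arma::cube& dy, const arma::cube& y,
                    const arma::mat& xhat, const arma::vec& gamma,
                    const arma::vec& inv_sd, bool train) {
  const int hw = dy.n_rows * dy.n_cols, C = dy.n_slices;
  arma::mat D(const_cast<double*>(dy.memptr()), hw, C, false);
  arma::mat Ym(const_cast<double*>(y.memptr()), hw, C, false);
  arma::mat Dm = D % (Ym > 0);               // ReLU mask
  arma::rowvec dgamma = arma::sum(Dm % xhat, 0);
  arma::rowvec dbeta = arma::sum(Dm, 0);
  arma::mat dxhat = Dm;
  dxhat.each_row() %= gamma.t();
  arma::mat dxm;
  if (train) {
    arma::rowvec t1 = arma::mean(dxhat, 0);
    arma::rowvec t2 = arma::mean(dxhat % xhat, 0);
    dxm = dxhat;
    dxm.each_row() -= t1;
    dxm -= xhat.each_row() % t2;
    dxm.each_row() %= inv_sd.t();
  } else {
    dxm = dxhat;
    dxm.each_row() %= inv_sd.t();
  }
  arma::cube dx(dxm.memptr(), dy.n_rows, dy.n_cols, C);
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma.t(),
                      _["dbeta"] = dbeta.t());
}
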
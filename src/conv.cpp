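// 2-D convolution kernels for the density-regression network.
// Tensor layout matches R arrays: dim = c(H, W, C), column-major, so an
// R array maps directly onto an arma::cube(H, W, C) without copying.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static cube as_cube(Rcpp::NumericVector v) {
  Rcpp::IntegerVector d = v.attr("dim");
  if (d.size() != 3) Rcpp::stop("expected a 3-d array (H, W, C)");
  return cube(v.begin(), d[0], d[1], d[2], false);
}

static Rcpp::NumericVector wrap_cube(const cube& c) {
  Rcpp::NumericVector out(c.begin(), c.end());
  out.attr("dim") = Rcpp::IntegerVector::create(c.n_rows, c.n_cols, c.n_slices);
  return out;
}

static int out_size(int n, int k, int stride, int pad, int dil) {
  int eff = dil * (k - 1) + 1;
  int o = (n + 2 * pad - eff) / stride + 1;
  if (o < 1) Rcpp::stop("convolution output would be empty");
  return o;
}

// Unfold input patches into a (Ho*Wo) x (kh*kw*C) matrix whose column
// ordering matches the (kh, kw, Cin, Cout) weight layout reshaped to
// (kh*kw*Cin, Cout).
static mat im2col(const cube& X, int kh, int kw, int stride, int pad,
                  int dil, int Ho, int Wo) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  mat M(static_cast<uword>(Ho) * Wo, static_cast<uword>(kh) * kw * C,
        fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < kw; ++kj)
      for (int ki = 0; ki < kh; ++ki) {
        const uword col = ki + kj * kh + static_cast<uword>(c) * kh * kw;
        for (int oj = 0; oj < Wo; ++oj) {
          const int j = oj * stride - pad + kj * dil;
          if (j < 0 || j >= W) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            const int i = oi * stride - pad + ki * dil;
            if (i < 0 || i >= H) continue;
            M(oi + static_cast<uword>(oj) * Ho, col) = X(i, j, c);
          }
        }
      }
  return M;
}

// Scatter-add the unfolded gradient back onto the input grid (transpose
// of im2col).
static cube col2im(const mat& M, int H, int W, int C, int kh, int kw,
                   int stride, int pad, int dil, int Ho, int Wo) {
  cube G(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < kw; ++kj)
      for (int ki = 0; ki < kh; ++ki) {
        const uword col = ki + kj * kh + static_cast<uword>(c) * kh * kw;
        for (int oj = 0; oj < Wo; ++oj) {
          const int j = oj * stride - pad + kj * dil;
          if (j < 0 || j >= W) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            const int i = oi * stride - pad + ki * dil;
            if (i < 0 || i >= H) continue;
            G(i, j, c) += M(oi + static_cast<uword>(oj) * Ho, col);
          }
        }
      }
  return G;
}

static mat weight_mat(Rcpp::NumericVector w, int& kh, int& kw, int& cin,
                      int& cout) {
  Rcpp::IntegerVector d = w.attr("dim");
  if (d.size() != 4) Rcpp::stop("weights must be a 4-d array (kh,kw,Cin,Cout)");
  kh = d[0]; kw = d[1]; cin = d[2]; cout = d[3];
  return mat(w.begin(), static_cast<uword>(kh) * kw * cin, cout, false);
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_conv2d(Rcpp::NumericVector input,
                               Rcpp::NumericVector weights,
                               Rcpp::NumericVector bias,
                               int stride, int pad, int dil) {
  cube X = as_cube(input);
  int kh, kw, cin, cout;
  mat Wm = weight_mat(weights, kh, kw, cin, cout);
  if (static_cast<int>(X.n_slices) != cin)
    Rcpp::stop("input channels do not match weights");
  const int Ho = out_size(X.n_rows, kh, stride, pad, dil);
  const int Wo = out_size(X.n_cols, kw, stride, pad, dil);
  mat M = im2col(X, kh, kw, stride, pad, dil, Ho, Wo);
  mat Y = M * Wm;
  Y.each_row() += rowvec(bias.begin(), cout, false);
  cube out(Y.memptr(), Ho, Wo, cout);
  return wrap_cube(out);
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_backward(Rcpp::NumericVector input,
                               Rcpp::NumericVector weights,
                               Rcpp::NumericVector grad_out,
                               int stride, int pad, int dil) {
  cube X = as_cube(input);
  cube GO = as_cube(grad_out);
  int kh, kw, cin, cout;
  mat Wm = weight_mat(weights, kh, kw, cin, cout);
  const int Ho = GO.n_rows, Wo = GO.n_cols;
  mat G(GO.memptr(), static_cast<uword>(Ho) * Wo, cout, false);
  mat M = im2col(X, kh, kw, stride, pad, dil, Ho, Wo);
  mat gw = M.t() * G;                       // (kh*kw*cin) x cout
  rowvec gb = sum(G, 0);
  mat gcols = G * Wm.t();                   // (Ho*Wo) x (kh*kw*cin)
  cube gx = col2im(gcols, X.n_rows, X.n_cols, cin, kh, kw, stride, pad,
                   dil, Ho, Wo);
  Rcpp::NumericVector gwv(gw.begin(), gw.end());
  gwv.attr("dim") = Rcpp::IntegerVector::create(kh, kw, cin, cout);
  return Rcpp::List::create(Rcpp::Named("gx") = wrap_cube(gx),
                            Rcpp::Named("gw") = gwv,
                            Rcpp::Named("gb") =
                              Rcpp::NumericVector(gb.begin(), gb.end()));
}

// Nearest-neighbour resampling to an arbitrary target size (used both for
// the x2 decoder upsampling and the final enlargement to the input size).
// [[Rcpp::export]]
Rcpp::NumericVector cpp_resample_nearest(Rcpp::NumericVector input,
                                         int out_h, int out_w) {
  cube X = as_cube(input);
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  cube Y(out_h, out_w, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < out_w; ++j) {
      const int sj = std::min(W - 1, j * W / out_w);
      for (int i = 0; i < out_h; ++i) {
        const int si = std::min(H - 1, i * H / out_h);
        Y(i, j, c) = X(si, sj, c);
      }
    }
  return wrap_cube(Y);
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_resample_nearest_backward(Rcpp::NumericVector grad_out,
                                                  int in_h, int in_w) {
  cube GO = as_cube(grad_out);
  const int Ho = GO.n_rows, Wo = GO.n_cols, C = GO.n_slices;
  cube G(in_h, in_w, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j) {
      const int sj = std::min(in_w - 1, j * in_w / Wo);
      for (int i = 0; i < Ho; ++i) {
        const int si = std::min(in_h - 1, i * in_h / Ho);
        G(si, sj, c) += GO(i, j, c);
      }
    }
  return wrap_cube(G);
}
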
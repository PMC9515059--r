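// Small convolutional backbone for beam-weight regression:
//   conv(C->F1, 5x5, stride 2, pad 2) + ReLU
//   conv(F1->F2, 3x3, stride 2, pad 1) + ReLU
//   flatten -> fc(F2*OH2^2 -> F3) + ReLU -> fc(F3 -> 1)
// Hand-written forward/backward (im2col); the optimiser (Adam) and the
// coverage-weighted loss live on the R side, which supplies dL/dout.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct ConvDims {
  int H, C, K, stride, pad, OH;
};

// input X: (H*H, C); col: (C*K*K, OH*OH)
void im2col(const mat &X, const ConvDims &d, mat &col) {
  col.zeros(d.C * d.K * d.K, d.OH * d.OH);
  for (int ow = 0; ow < d.OH; ++ow)
    for (int oh = 0; oh < d.OH; ++oh) {
      int cc = oh + d.OH * ow;
      for (int kw = 0; kw < d.K; ++kw) {
        int w = ow * d.stride + kw - d.pad;
        if (w < 0 || w >= d.H) continue;
        for (int kh = 0; kh < d.K; ++kh) {
          int h = oh * d.stride + kh - d.pad;
          if (h < 0 || h >= d.H) continue;
          for (int c = 0; c < d.C; ++c)
            col(c * d.K * d.K + kh * d.K + kw, cc) = X(h + d.H * w, c);
        }
      }
    }
}

void col2im(const mat &dcol, const ConvDims &d, mat &dX) {
  dX.zeros(d.H * d.H, d.C);
  for (int ow = 0; ow < d.OH; ++ow)
    for (int oh = 0; oh < d.OH; ++oh) {
      int cc = oh + d.OH * ow;
      for (int kw = 0; kw < d.K; ++kw) {
        int w = ow * d.stride + kw - d.pad;
        if (w < 0 || w >= d.H) continue;
        for (int kh = 0; kh < d.K; ++kh) {
          int h = oh * d.stride + kh - d.pad;
          if (h < 0 || h >= d.H) continue;
          for (int c = 0; c < d.C; ++c)
            dX(h + d.H * w, c) += dcol(c * d.K * d.K + kh * d.K + kw, cc);
        }
      }
    }
}

inline int out_dim(int H, int K, int stride, int pad) {
  return (H + 2 * pad - K) / stride + 1;
}

}  // namespace

// X: (H*H*C) x N batch of feature images (layout of dim c(H, H, C) arrays).
// Returns predictions and, when dout is non-empty, parameter gradients.
// [[Rcpp::export(name = ".net_run_cpp")]]
Rcpp::List net_run_cpp(Rcpp::List params, const arma::mat &X, int H, int C,
                       const arma::vec &dout) {
  mat W1 = params["W1"]; vec b1 = params["b1"];
  mat W2 = params["W2"]; vec b2 = params["b2"];
  mat W4 = params["W4"]; vec b4 = params["b4"];
  mat W5 = params["W5"]; vec b5 = params["b5"];
  const int F1 = W1.n_rows, F2 = W2.n_rows, F3 = W4.n_rows;
  const int N = X.n_cols;
  const bool grad = dout.n_elem > 0;

  ConvDims d1{H, C, 5, 2, 2, out_dim(H, 5, 2, 2)};
  ConvDims d2{d1.OH, F1, 3, 2, 1, out_dim(d1.OH, 3, 2, 1)};

  vec pred(N, fill::zeros);
  mat dW1(size(W1), fill::zeros), dW2(size(W2), fill::zeros),
      dW4(size(W4), fill::zeros), dW5(size(W5), fill::zeros);
  vec db1(F1, fill::zeros), db2(F2, fill::zeros), db4(F3, fill::zeros),
      db5(1, fill::zeros);

  mat col1, col2, dcol, dX1;
  for (int n = 0; n < N; ++n) {
    mat X0(const_cast<double *>(X.colptr(n)), H * H, C, false, true);
    im2col(X0, d1, col1);
    mat Y1 = W1 * col1;
    Y1.each_col() += b1;                       // F1 x OH1^2
    mat A1 = clamp(Y1, 0.0, datum::inf).t();   // OH1^2 x F1
    im2col(A1, d2, col2);
    mat Y2 = W2 * col2;
    Y2.each_col() += b2;                       // F2 x OH2^2
    mat A2 = clamp(Y2, 0.0, datum::inf);
    vec g = vectorise(A2);                     // flatten F2 x OH2^2
    vec h = W4 * g + b4;
    vec hr = clamp(h, 0.0, datum::inf);
    double out = as_scalar(W5 * hr) + b5[0];
    pred[n] = out;
    if (!grad) continue;

    double do_n = dout[n];
    vec dhr = W5.t() * do_n;
    dW5 += do_n * hr.t();
    db5[0] += do_n;
    vec dh = dhr % conv_to<vec>::from(h > 0);
    dW4 += dh * g.t();
    db4 += dh;
    vec dg = W4.t() * dh;
    mat dA2 = reshape(dg, F2, A2.n_cols);
    mat dY2 = dA2 % conv_to<mat>::from(Y2 > 0);
    dW2 += dY2 * col2.t();
    db2 += sum(dY2, 1);
    dcol = W2.t() * dY2;
    col2im(dcol, d2, dX1);                     // dX1: OH1^2 x F1
    mat dY1 = dX1.t() % conv_to<mat>::from(Y1 > 0);
    dW1 += dY1 * col1.t();
    db1 += sum(dY1, 1);
  }

  if (!grad) return Rcpp::List::create(Rcpp::Named("pred") = pred);
  return Rcpp::List::create(
      Rcpp::Named("pred") = pred,
      Rcpp::Named("grads") = Rcpp::List::create(
          Rcpp::Named("W1") = dW1, Rcpp::Named("b1") = db1,
          Rcpp::Named("W2") = dW2, Rcpp::Named("b2") = db2,
          Rcpp::Named("W4") = dW4, Rcpp::Named("b4") = db4,
          Rcpp::Named("W5") = dW5, Rcpp::Named("b5") = db5));
}
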
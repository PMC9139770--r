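// Minimal volumetric convolution engine used by the density and parameter
// networks. Feature maps are R arrays (x, y, z, channels), column-major;
// convolution weights are arrays (kx, ky, kz, c_in, c_out). Forward and
// backward passes are expressed as im2col + GEMM. A 2D problem is a volume
// with a singleton z axis (kernel extent 1, stride 1 along it).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static void im2col(const double* x, const int* xd, const int* kd,
                   const int* stride, const int* pad, const int* od,
                   arma::mat& col) {
  const int cin = xd[3];
  const int nr = od[0] * od[1] * od[2];
  col.set_size(nr, kd[0] * kd[1] * kd[2] * cin);
  for (int ci = 0; ci < cin; ++ci)
    for (int dz = 0; dz < kd[2]; ++dz)
      for (int dy = 0; dy < kd[1]; ++dy)
        for (int dx = 0; dx < kd[0]; ++dx) {
          const int cc = dx + kd[0] * (dy + kd[1] * (dz + kd[2] * ci));
          double* dst = col.colptr(cc);
          for (int oz = 0; oz < od[2]; ++oz) {
            const int zi = oz * stride[2] - pad[2] + dz;
            for (int oy = 0; oy < od[1]; ++oy) {
              const int yi = oy * stride[1] - pad[1] + dy;
              const int rbase = od[0] * (oy + od[1] * oz);
              if (zi < 0 || zi >= xd[2] || yi < 0 || yi >= xd[1]) {
                for (int ox = 0; ox < od[0]; ++ox) dst[rbase + ox] = 0.0;
                continue;
              }
              const double* src =
                x + (size_t)xd[0] * (yi + (size_t)xd[1] * (zi + (size_t)xd[2] * ci));
              for (int ox = 0; ox < od[0]; ++ox) {
                const int xi = ox * stride[0] - pad[0] + dx;
                dst[rbase + ox] = (xi >= 0 && xi < xd[0]) ? src[xi] : 0.0;
              }
            }
          }
        }
}

static void out_dims(const int* xd, const int* kd, const int* stride,
                     const int* pad, int* od) {
  for (int i = 0; i < 3; ++i)
    od[i] = (xd[i] + 2 * pad[i] - kd[i]) / stride[i] + 1;
}

// [[Rcpp::export]]
NumericVector conv_fwd_cpp(NumericVector x, IntegerVector xdim,
                           NumericVector w, IntegerVector wdim,
                           NumericVector b, IntegerVector stride,
                           IntegerVector pad) {
  const int xd[4] = {xdim[0], xdim[1], xdim[2], xdim[3]};
  const int kd[3] = {wdim[0], wdim[1], wdim[2]};
  const int cout = wdim[4];
  int od[3];
  out_dims(xd, kd, stride.begin(), pad.begin(), od);
  const int nr = od[0] * od[1] * od[2];
  arma::mat col;
  im2col(x.begin(), xd, kd, stride.begin(), pad.begin(), od, col);
  arma::mat W(w.begin(), col.n_cols, cout, false, true);
  NumericVector y(nr * cout);
  arma::mat Y(y.begin(), nr, cout, false, true);
  Y = col * W;
  for (int co = 0; co < cout; ++co) Y.col(co) += b[co];
  y.attr("dim") = IntegerVector::create(od[0], od[1], od[2], cout);
  return y;
}

// [[Rcpp::export]]
List conv_bwd_cpp(NumericVector x, IntegerVector xdim,
                  NumericVector w, IntegerVector wdim,
                  IntegerVector stride, IntegerVector pad,
                  NumericVector dy) {
  const int xd[4] = {xdim[0], xdim[1], xdim[2], xdim[3]};
  const int kd[3] = {wdim[0], wdim[1], wdim[2]};
  const int cin = wdim[3], cout = wdim[4];
  int od[3];
  out_dims(xd, kd, stride.begin(), pad.begin(), od);
  const int nr = od[0] * od[1] * od[2];

  arma::mat col;
  im2col(x.begin(), xd, kd, stride.begin(), pad.begin(), od, col);
  arma::mat dY(dy.begin(), nr, cout, false, true);
  arma::mat W(w.begin(), col.n_cols, cout, false, true);

  NumericVector dw(w.size());
  arma::mat dW(dw.begin(), col.n_cols, cout, false, true);
  dW = col.t() * dY;
  dw.attr("dim") = wdim;

  NumericVector db(cout);
  for (int co = 0; co < cout; ++co) db[co] = arma::accu(dY.col(co));

  arma::mat dcol = dY * W.t();   // nr x kcols
  NumericVector dx(x.size());
  double* dxp = dx.begin();
  for (int ci = 0; ci < cin; ++ci)
    for (int dz = 0; dz < kd[2]; ++dz)
      for (int dyk = 0; dyk < kd[1]; ++dyk)
        for (int dxk = 0; dxk < kd[0]; ++dxk) {
          const int cc = dxk + kd[0] * (dyk + kd[1] * (dz + kd[2] * ci));
          const double* src = dcol.colptr(cc);
          for (int oz = 0; oz < od[2]; ++oz) {
            const int zi = oz * stride[2] - pad[2] + dz;
            if (zi < 0 || zi >= xd[2]) continue;
            for (int oy = 0; oy < od[1]; ++oy) {
              const int yi = oy * stride[1] - pad[1] + dyk;
              if (yi < 0 || yi >= xd[1]) continue;
              double* dst =
                dxp + (size_t)xd[0] * (yi + (size_t)xd[1] * (zi + (size_t)xd[2] * ci));
              const int rbase = od[0] * (oy + od[1] * oz);
              for (int ox = 0; ox < od[0]; ++ox) {
                const int xi = ox * stride[0] - pad[0] + dxk;
                if (xi >= 0 && xi < xd[0]) dst[xi] += src[rbase + ox];
              }
            }
          }
        }
  dx.attr("dim") = xdim;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Forward pass that also returns the im2col matrix so the backward pass
// can reuse it instead of rebuilding it (training-time path).
// [[Rcpp::export]]
List conv_fwd_col_cpp(NumericVector x, IntegerVector xdim,
                      NumericVector w, IntegerVector wdim,
                      NumericVector b, IntegerVector stride,
                      IntegerVector pad) {
  const int xd[4] = {xdim[0], xdim[1], xdim[2], xdim[3]};
  const int kd[3] = {wdim[0], wdim[1], wdim[2]};
  const int cout = wdim[4];
  int od[3];
  out_dims(xd, kd, stride.begin(), pad.begin(), od);
  const int nr = od[0] * od[1] * od[2];
  arma::mat colm;
  im2col(x.begin(), xd, kd, stride.begin(), pad.begin(), od, colm);
  arma::mat W(w.begin(), colm.n_cols, cout, false, true);
  NumericVector y(nr * cout);
  arma::mat Y(y.begin(), nr, cout, false, true);
  Y = colm * W;
  for (int co = 0; co < cout; ++co) Y.col(co) += b[co];
  y.attr("dim") = IntegerVector::create(od[0], od[1], od[2], cout);
  NumericMatrix colr(colm.n_rows, colm.n_cols);
  std::copy(colm.begin(), colm.end(), colr.begin());
  return List::create(_["y"] = y, _["col"] = colr);
}

// Backward pass reusing a stored im2col matrix.
// [[Rcpp::export]]
List conv_bwd_col_cpp(NumericMatrix colr, IntegerVector xdim,
                      NumericVector w, IntegerVector wdim,
                      IntegerVector stride, IntegerVector pad,
                      NumericVector dy) {
  const int xd[4] = {xdim[0], xdim[1], xdim[2], xdim[3]};
  const int kd[3] = {wdim[0], wdim[1], wdim[2]};
  const int cin = wdim[3], cout = wdim[4];
  int od[3];
  out_dims(xd, kd, stride.begin(), pad.begin(), od);
  const int nr = od[0] * od[1] * od[2];

  arma::mat colm(colr.begin(), colr.nrow(), colr.ncol(), false, true);
  arma::mat dY(dy.begin(), nr, cout, false, true);
  arma::mat W(w.begin(), colm.n_cols, cout, false, true);

  NumericVector dw(w.size());
  arma::mat dW(dw.begin(), colm.n_cols, cout, false, true);
  dW = colm.t() * dY;
  dw.attr("dim") = wdim;

  NumericVector db(cout);
  for (int co = 0; co < cout; ++co) db[co] = arma::accu(dY.col(co));

  arma::mat dcol = dY * W.t();
  NumericVector dx((size_t)xd[0] * xd[1] * xd[2] * xd[3]);
  double* dxp = dx.begin();
  for (int ci = 0; ci < cin; ++ci)
    for (int dz = 0; dz < kd[2]; ++dz)
      for (int dyk = 0; dyk < kd[1]; ++dyk)
        for (int dxk = 0; dxk < kd[0]; ++dxk) {
          const int cc = dxk + kd[0] * (dyk + kd[1] * (dz + kd[2] * ci));
          const double* src = dcol.colptr(cc);
          for (int oz = 0; oz < od[2]; ++oz) {
            const int zi = oz * stride[2] - pad[2] + dz;
            if (zi < 0 || zi >= xd[2]) continue;
            for (int oy = 0; oy < od[1]; ++oy) {
              const int yi = oy * stride[1] - pad[1] + dyk;
              if (yi < 0 || yi >= xd[1]) continue;
              double* dst =
                dxp + (size_t)xd[0] * (yi + (size_t)xd[1] * (zi + (size_t)xd[2] * ci));
              const int rbase = od[0] * (oy + od[1] * oz);
              for (int ox = 0; ox < od[0]; ++ox) {
                const int xi = ox * stride[0] - pad[0] + dxk;
                if (xi >= 0 && xi < xd[0]) dst[xi] += src[rbase + ox];
              }
            }
          }
        }
  dx.attr("dim") = xdim;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Transposed convolution with kernel extent equal to stride per axis
// (non-overlapping up-sampling, as in 2x2 stride-2 U-Net up blocks).
// [[Rcpp::export]]
NumericVector tconv_fwd_cpp(NumericVector x, IntegerVector xdim,
                            NumericVector w, IntegerVector wdim,
                            NumericVector b, IntegerVector stride) {
  const int xd[4] = {xdim[0], xdim[1], xdim[2], xdim[3]};
  const int kd[3] = {wdim[0], wdim[1], wdim[2]};
  const int cin = wdim[3], cout = wdim[4];
  const int nin = xd[0] * xd[1] * xd[2];
  const int odx = xd[0] * stride[0], ody = xd[1] * stride[1],
            odz = xd[2] * stride[2];
  arma::mat X(x.begin(), nin, cin, false, true);
  NumericVector y((size_t)odx * ody * odz * cout);
  double* yp = y.begin();
  arma::mat Woff(cin, cout);
  arma::mat Yoff(nin, cout);
  for (int dz = 0; dz < kd[2]; ++dz)
    for (int dyk = 0; dyk < kd[1]; ++dyk)
      for (int dxk = 0; dxk < kd[0]; ++dxk) {
        for (int ci = 0; ci < cin; ++ci)
          for (int co = 0; co < cout; ++co)
            Woff(ci, co) = w[dxk + kd[0] * (dyk + kd[1] * (dz + kd[2] *
                             (ci + (size_t)cin * co)))];
        Yoff = X * Woff;
        for (int co = 0; co < cout; ++co)
          for (int z = 0; z < xd[2]; ++z)
            for (int yy = 0; yy < xd[1]; ++yy)
              for (int xx = 0; xx < xd[0]; ++xx) {
                const size_t oi = (size_t)(xx * stride[0] + dxk) +
                  (size_t)odx * ((yy * stride[1] + dyk) +
                  (size_t)ody * ((z * stride[2] + dz) + (size_t)odz * co));
                yp[oi] = Yoff(xx + xd[0] * (yy + xd[1] * z), co) + b[co];
              }
      }
  y.attr("dim") = IntegerVector::create(odx, ody, odz, cout);
  return y;
}

// [[Rcpp::export]]
List tconv_bwd_cpp(NumericVector x, IntegerVector xdim,
                   NumericVector w, IntegerVector wdim,
                   IntegerVector stride, NumericVector dy) {
  const int xd[4] = {xdim[0], xdim[1], xdim[2], xdim[3]};
  const int kd[3] = {wdim[0], wdim[1], wdim[2]};
  const int cin = wdim[3], cout = wdim[4];
  const int nin = xd[0] * xd[1] * xd[2];
  const int odx = xd[0] * stride[0], ody = xd[1] * stride[1],
            odz = xd[2] * stride[2];
  arma::mat X(x.begin(), nin, cin, false, true);
  NumericVector dx(x.size());
  arma::mat dX(dx.begin(), nin, cin, false, true);
  NumericVector dw(w.size());
  NumericVector db(cout);
  const double* dyp = dy.begin();
  arma::mat dYoff(nin, cout);
  for (int dz = 0; dz < kd[2]; ++dz)
    for (int dyk = 0; dyk < kd[1]; ++dyk)
      for (int dxk = 0; dxk < kd[0]; ++dxk) {
        for (int co = 0; co < cout; ++co)
          for (int z = 0; z < xd[2]; ++z)
            for (int yy = 0; yy < xd[1]; ++yy)
              for (int xx = 0; xx < xd[0]; ++xx) {
                const size_t oi = (size_t)(xx * stride[0] + dxk) +
                  (size_t)odx * ((yy * stride[1] + dyk) +
                  (size_t)ody * ((z * stride[2] + dz) + (size_t)odz * co));
                dYoff(xx + xd[0] * (yy + xd[1] * z), co) = dyp[oi];
              }
        arma::mat Woff(cin, cout);
        for (int ci = 0; ci < cin; ++ci)
          for (int co = 0; co < cout; ++co)
            Woff(ci, co) = w[dxk + kd[0] * (dyk + kd[1] * (dz + kd[2] *
                             (ci + (size_t)cin * co)))];
        dX += dYoff * Woff.t();
        arma::mat dWoff = X.t() * dYoff;
        for (int ci = 0; ci < cin; ++ci)
          for (int co = 0; co < cout; ++co)
            dw[dxk + kd[0] * (dyk + kd[1] * (dz + kd[2] *
               (ci + (size_t)cin * co)))] = dWoff(ci, co);
        for (int co = 0; co < cout; ++co) db[co] += arma::accu(dYoff.col(co));
      }
  dx.attr("dim") = xdim;
  dw.attr("dim") = wdim;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
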
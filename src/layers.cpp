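// Low-level numeric kernels for the 3D network: convolution, max-pooling,
// dot-product attention and 6-connected component labelling.
//
// Volumes are stored column-major as (X, Y, Z, C, B): voxel index fastest,
// then channel, then batch sample.  A (X*Y*Z x C) slice of one sample is
// therefore a contiguous column-major matrix, which the attention kernels
// exploit directly.

#include <RcppArmadillo.h>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Build the (N x k^3*Cin) patch matrix for one sample (zero "same" padding).
static arma::mat im2col(const double* xb, int X, int Y, int Z, int Cin, int k) {
  const int p = k / 2, N = X * Y * Z, k3 = k * k * k;
  arma::mat col(N, (arma::uword)(k3 * Cin), arma::fill::zeros);
  for (int ci = 0; ci < Cin; ++ci) {
    const double* chan = xb + (size_t)ci * N;
    for (int dz = -p; dz <= p; ++dz)
      for (int dy = -p; dy <= p; ++dy)
        for (int dx = -p; dx <= p; ++dx) {
          const int o = (dx + p) + k * ((dy + p) + k * (dz + p));
          double* dst = col.colptr(o + k3 * ci);
          for (int z = 0; z < Z; ++z) {
            const int sz = z + dz;
            if (sz < 0 || sz >= Z) continue;
            for (int y = 0; y < Y; ++y) {
              const int sy = y + dy;
              if (sy < 0 || sy >= Y) continue;
              const int x0 = std::max(0, -dx), x1 = std::min(X, X - dx);
              const double* src = chan + ((size_t)sz * Y + sy) * X;
              double* d = dst + ((size_t)z * Y + y) * X;
              for (int x = x0; x < x1; ++x) d[x] = src[x + dx];
            }
          }
        }
  }
  return col;
}

// Scatter-add the transpose of im2col: accumulate patch-gradients into dX.
static void col2im_add(const arma::mat& dcol, double* dxb,
                       int X, int Y, int Z, int Cin, int k) {
  const int p = k / 2, N = X * Y * Z, k3 = k * k * k;
  for (int ci = 0; ci < Cin; ++ci) {
    double* chan = dxb + (size_t)ci * N;
    for (int dz = -p; dz <= p; ++dz)
      for (int dy = -p; dy <= p; ++dy)
        for (int dx = -p; dx <= p; ++dx) {
          const int o = (dx + p) + k * ((dy + p) + k * (dz + p));
          const double* s = dcol.colptr(o + k3 * ci);
          for (int z = 0; z < Z; ++z) {
            const int sz = z + dz;
            if (sz < 0 || sz >= Z) continue;
            for (int y = 0; y < Y; ++y) {
              const int sy = y + dy;
              if (sy < 0 || sy >= Y) continue;
              const int x0 = std::max(0, -dx), x1 = std::min(X, X - dx);
              double* dchan = chan + ((size_t)sz * Y + sy) * X;
              const double* sp = s + ((size_t)z * Y + y) * X;
              for (int x = x0; x < x1; ++x) dchan[x + dx] += sp[x];
            }
          }
        }
  }
}

// Stride-1, zero-padded ("same") 3D convolution.
// x: (X,Y,Z,Cin,B); w: (k,k,k,Cin,Cout) flattened; bias: length Cout.
// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector xdim,
                             NumericVector w, NumericVector bias, int k) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], Cin = xdim[3], B = xdim[4];
  const int N = X * Y * Z, k3 = k * k * k, Cout = bias.size();
  arma::mat W((double*)w.begin(), (arma::uword)(k3 * Cin), Cout, false, true);
  NumericVector out((R_xlen_t)N * Cout * B);
  for (int b = 0; b < B; ++b) {
    arma::mat col = im2col(x.begin() + (size_t)b * N * Cin, X, Y, Z, Cin, k);
    arma::mat Yb(out.begin() + (size_t)b * N * Cout, N, Cout, false, true);
    Yb = col * W;
    for (int co = 0; co < Cout; ++co) Yb.col(co) += bias[co];
  }
  out.attr("dim") = IntegerVector::create(X, Y, Z, Cout, B);
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, IntegerVector xdim, NumericVector w,
                    NumericVector dy, int k, int cout) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], Cin = xdim[3], B = xdim[4];
  const int N = X * Y * Z, k3 = k * k * k;
  arma::mat W((double*)w.begin(), (arma::uword)(k3 * Cin), cout, false, true);
  NumericVector dxv((R_xlen_t)N * Cin * B);  // zero-initialised
  arma::mat dW((arma::uword)(k3 * Cin), cout, arma::fill::zeros);
  arma::rowvec db(cout, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    arma::mat col = im2col(x.begin() + (size_t)b * N * Cin, X, Y, Z, Cin, k);
    arma::mat dYb((double*)dy.begin() + (size_t)b * N * cout, N, cout, false, true);
    dW += col.t() * dYb;
    db += arma::sum(dYb, 0);
    arma::mat dcol = dYb * W.t();
    col2im_add(dcol, dxv.begin() + (size_t)b * N * Cin, X, Y, Z, Cin, k);
  }
  dxv.attr("dim") = IntegerVector::create(X, Y, Z, Cin, B);
  return List::create(_["dx"] = dxv, _["dw"] = wrap(dW), _["db"] = wrap(db));
}

// 2x2x2 max-pool, stride 2.  Returns pooled values and 1-based argmax
// indices into the input vector (first-maximum tie rule, deterministic).
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, IntegerVector xdim) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3], B = xdim[4];
  const int Xo = X / 2, Yo = Y / 2, Zo = Z / 2;
  const size_t Nin = (size_t)X * Y * Z, No = (size_t)Xo * Yo * Zo;
  NumericVector out((R_xlen_t)(No * C * B));
  IntegerVector am(out.size());
  size_t oi = 0;
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)b * C + c) * Nin;
      const double* ch = x.begin() + base;
      for (int z = 0; z < Zo; ++z)
        for (int y = 0; y < Yo; ++y)
          for (int xo = 0; xo < Xo; ++xo) {
            double best = -std::numeric_limits<double>::infinity();
            size_t bi = 0;
            for (int dz = 0; dz < 2; ++dz)
              for (int dy = 0; dy < 2; ++dy)
                for (int dx = 0; dx < 2; ++dx) {
                  const size_t ii = ((size_t)(2 * z + dz) * Y + (2 * y + dy)) * X
                                    + (2 * xo + dx);
                  if (ch[ii] > best) { best = ch[ii]; bi = ii; }
                }
            out[oi] = best;
            am[oi] = (int)(base + bi) + 1;
            ++oi;
          }
    }
  out.attr("dim") = IntegerVector::create(Xo, Yo, Zo, C, B);
  return List::create(_["y"] = out, _["argmax"] = am);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(IntegerVector argmax, NumericVector dy,
                              IntegerVector xdim) {
  R_xlen_t n = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3] * xdim[4];
  NumericVector dx(n);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[argmax[i] - 1] += dy[i];
  dx.attr("dim") = xdim;
  return dx;
}

// Column-wise softmax (columns are contiguous in Armadillo's column-major
// storage; scores are held transposed so each query's scores form a column).
static void softmax_cols(arma::mat& St) {
  const arma::uword n = St.n_rows;
  for (arma::uword j = 0; j < St.n_cols; ++j) {
    double* col = St.colptr(j);
    double m = col[0];
    for (arma::uword i = 1; i < n; ++i) m = std::max(m, col[i]);
    double s = 0.0;
    for (arma::uword i = 0; i < n; ++i) { col[i] = std::exp(col[i] - m); s += col[i]; }
    const double inv = 1.0 / s;
    for (arma::uword i = 0; i < n; ++i) col[i] *= inv;
  }
}

// Dot-product attention over flattened spatial positions.
// q, v: (N, C, B).  scores S = Q V' (optionally / sqrt(C)); out = softmax(S) V.
// `chunk` bounds the number of queries whose scores are materialised at once
// (<=0: all N).  Scores are held transposed (value index down the columns).
// [[Rcpp::export]]
NumericVector cpp_attention_fwd(NumericVector q, NumericVector v,
                                IntegerVector dim, bool use_scale, int chunk) {
  const int N = dim[0], C = dim[1], B = dim[2];
  const double sc = use_scale ? 1.0 / std::sqrt((double)C) : 1.0;
  if (chunk <= 0) chunk = N;
  NumericVector out((R_xlen_t)N * C * B);
  for (int b = 0; b < B; ++b) {
    arma::mat Q((double*)q.begin() + (size_t)b * N * C, N, C, false, true);
    arma::mat V((double*)v.begin() + (size_t)b * N * C, N, C, false, true);
    arma::mat O(out.begin() + (size_t)b * N * C, N, C, false, true);
    for (int r0 = 0; r0 < N; r0 += chunk) {
      const int r1 = std::min(N, r0 + chunk) - 1;
      arma::mat St = V * (sc * Q.rows(r0, r1)).t();  // N x m, col j = query r0+j
      softmax_cols(St);
      O.rows(r0, r1) = St.t() * V;
    }
  }
  out.attr("dim") = dim;
  return out;
}

// [[Rcpp::export]]
List cpp_attention_bwd(NumericVector q, NumericVector v, NumericVector dout,
                       IntegerVector dim, bool use_scale, int chunk) {
  const int N = dim[0], C = dim[1], B = dim[2];
  const double sc = use_scale ? 1.0 / std::sqrt((double)C) : 1.0;
  if (chunk <= 0) chunk = N;
  NumericVector dqv((R_xlen_t)N * C * B), dvv((R_xlen_t)N * C * B);
  for (int b = 0; b < B; ++b) {
    arma::mat Q((double*)q.begin() + (size_t)b * N * C, N, C, false, true);
    arma::mat V((double*)v.begin() + (size_t)b * N * C, N, C, false, true);
    arma::mat dO((double*)dout.begin() + (size_t)b * N * C, N, C, false, true);
    arma::mat dQ(dqv.begin() + (size_t)b * N * C, N, C, false, true);
    arma::mat dV(dvv.begin() + (size_t)b * N * C, N, C, false, true);
    for (int r0 = 0; r0 < N; r0 += chunk) {
      const int r1 = std::min(N, r0 + chunk) - 1;
      arma::mat St = V * (sc * Q.rows(r0, r1)).t();  // recompute scores (transposed)
      softmax_cols(St);                              // -> weights W^T
      dV += St * dO.rows(r0, r1);                    // from O = W V
      arma::mat dWt = V * dO.rows(r0, r1).t();       // (dW)^T, N x m
      arma::rowvec rs = arma::sum(dWt % St, 0);      // per-query sum of dW*W
      arma::mat dSt = St % (dWt.each_row() - rs);    // softmax Jacobian, transposed
      dSt *= sc;
      dQ.rows(r0, r1) = dSt.t() * V;
      dV += dSt * Q.rows(r0, r1);
    }
  }
  dqv.attr("dim") = dim;
  dvv.attr("dim") = dim;
  return List::create(_["dq"] = dqv, _["dv"] = dvv);
}

// 6-connected component labelling of a 3D logical mask.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim) {
  const int X = dim[0], Y = dim[1], Z = dim[2];
  const size_t N = (size_t)X * Y * Z;
  IntegerVector lab((R_xlen_t)N);
  int cur = 0;
  std::vector<size_t> stack;
  const int nb[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (size_t s = 0; s < N; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    lab[s] = cur;
    stack.push_back(s);
    while (!stack.empty()) {
      const size_t i = stack.back();
      stack.pop_back();
      const int x = (int)(i % X), y = (int)((i / X) % Y), z = (int)(i / ((size_t)X * Y));
      for (int d = 0; d < 6; ++d) {
        const int nx = x + nb[d][0], ny = y + nb[d][1], nz = z + nb[d][2];
        if (nx < 0 || nx >= X || ny < 0 || ny >= Y || nz < 0 || nz >= Z) continue;
        const size_t j = ((size_t)nz * Y + ny) * X + nx;
        if (mask[j] && !lab[j]) { lab[j] = cur; stack.push_back(j); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
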
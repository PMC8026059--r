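// Hot layer primitives for the distogram network: im2col 3x3 convolution,
// 1x1 convolution, and instance normalization, forward and backward.
// Feature maps are (L*L) x C matrices; shift index maps come precomputed
// from R (1-based source pixel per target pixel and offset, with a
// validity mask for zero padding).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// build the (P x 9*Cin) im2col matrix from X and the nine shift maps
static arma::mat build_xcol(const arma::mat& X, const IntegerMatrix& idx,
                            const LogicalMatrix& valid) {
  const arma::uword P = X.n_rows, C = X.n_cols;
  arma::mat Xcol(P, 9 * C, arma::fill::zeros);
  for (int o = 0; o < 9; ++o) {
    for (arma::uword p = 0; p < P; ++p) {
      if (valid(p, o)) {
        const arma::uword s = idx(p, o) - 1;
        for (arma::uword c = 0; c < C; ++c)
          Xcol(p, o * C + c) = X(s, c);
      }
    }
  }
  return Xcol;
}

// [[Rcpp::export]]
List cpp_conv3_fwd(const arma::mat& X, const arma::mat& W, const arma::vec& b,
                   const IntegerMatrix& idx, const LogicalMatrix& valid) {
  arma::mat Xcol = build_xcol(X, idx, valid);
  arma::mat y = Xcol * W;
  y.each_row() += b.t();
  return List::create(_["y"] = y, _["Xcol"] = Xcol);
}

// [[Rcpp::export]]
List cpp_conv3_bwd(const arma::mat& Xcol, const arma::mat& dY,
                   const arma::mat& W, const IntegerMatrix& idx,
                   const LogicalMatrix& valid) {
  const arma::uword P = dY.n_rows;
  const arma::uword C = W.n_rows / 9;       // input channels
  arma::mat dW = Xcol.t() * dY;
  arma::vec db = arma::sum(dY, 0).t();
  arma::mat dXcol = dY * W.t();
  arma::mat dX(P, C, arma::fill::zeros);
  for (int o = 0; o < 9; ++o) {
    for (arma::uword p = 0; p < P; ++p) {
      if (valid(p, o)) {
        const arma::uword s = idx(p, o) - 1;
        for (arma::uword c = 0; c < C; ++c)
          dX(s, c) += dXcol(p, o * C + c);
      }
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_conv1_fwd(const arma::mat& X, const arma::mat& W, const arma::vec& b) {
  arma::mat y = X * W;
  y.each_row() += b.t();
  return List::create(_["y"] = y);
}

// [[Rcpp::export]]
List cpp_conv1_bwd(const arma::mat& X, const arma::mat& dY, const arma::mat& W,
                   const bool need_dx) {
  arma::mat dW = X.t() * dY;
  arma::vec db = arma::sum(dY, 0).t();
  if (need_dx) {
    arma::mat dX = dY * W.t();
    return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
  }
  return List::create(_["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_inorm_fwd(const arma::mat& X, const arma::vec& g, const arma::vec& b) {
  const arma::uword P = X.n_rows;
  arma::rowvec mu = arma::mean(X, 0);
  arma::mat xc = X.each_row() - mu;
  arma::rowvec v = arma::sum(arma::square(xc), 0) / double(P);
  arma::rowvec inv = 1.0 / arma::sqrt(v + 1e-5);
  arma::mat xhat = xc.each_row() % inv;
  arma::mat y = xhat.each_row() % g.t().eval();
  y.each_row() += b.t();
  return List::create(_["y"] = y, _["xhat"] = xhat,
                      _["inv"] = arma::vec(inv.t()));
}

// [[Rcpp::export]]
List cpp_inorm_bwd(const arma::mat& xhat, const arma::vec& inv,
                   const arma::vec& g, const arma::mat& dY) {
  const double n = double(xhat.n_rows);
  arma::vec dg = arma::sum(dY % xhat, 0).t();
  arma::vec db = arma::sum(dY, 0).t();
  arma::mat dxhat = dY.each_row() % g.t().eval();
  arma::rowvec t1 = arma::sum(dxhat, 0) / n;
  arma::rowvec t2 = arma::sum(dxhat % xhat, 0) / n;
  arma::mat dx = dxhat.each_row() - t1;
  dx -= xhat.each_row() % t2;
  dx.each_row() %= inv.t().eval();
  return List::create(_["dx"] = dx, _["dg"] = dg, _["db"] = db);
}
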
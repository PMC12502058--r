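// 3x3 same-padding convolution and 2x2 max-pooling kernels for the
// tiny_cnn backbone. Activations are (H*W, n, C) cubes; the convolution is
// 9 shifted GEMMs (one per kernel offset), mirroring the R reference
// layout: conv weights are (9*Cin) x Cout with rows channel-major, offset
// row-major within a channel.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// gather the padded cube's rows for offset j into an (hw*n x cin) matrix
static arma::mat gatherOffset(const arma::cube& P, const arma::uvec& nbrj,
    arma::uword hw, arma::uword n, arma::uword cin) {
  arma::mat g(hw * n, cin);
  for (arma::uword c = 0; c < cin; ++c) {
    const arma::mat& Pc = P.slice(c);
    for (arma::uword i = 0; i < n; ++i) {
      double* dst = g.colptr(c) + i * hw;
      const double* src = Pc.colptr(i);
      for (arma::uword p = 0; p < hw; ++p) dst[p] = src[nbrj[p]];
    }
  }
  return g;
}

static arma::cube padCube(const arma::cube& A, const arma::uvec& padPos,
    arma::uword pp) {
  arma::uword hw = A.n_rows, n = A.n_cols, cin = A.n_slices;
  arma::cube P(pp, n, cin, arma::fill::zeros);
  for (arma::uword c = 0; c < cin; ++c)
    for (arma::uword i = 0; i < n; ++i) {
      double* dst = P.slice(c).colptr(i);
      const double* src = A.slice(c).colptr(i);
      for (arma::uword p = 0; p < hw; ++p) dst[padPos[p]] = src[p];
    }
  return P;
}

// [[Rcpp::export(name = ".convForwardCpp")]]
arma::cube convForwardCpp(const arma::cube& A, const arma::mat& W,
    const arma::vec& b, const arma::umat& nbr, const arma::uvec& padPos,
    int pp) {
  arma::uword hw = A.n_rows, n = A.n_cols, cin = A.n_slices;
  arma::uword cout = W.n_cols;
  arma::cube P = padCube(A, padPos - 1, (arma::uword)pp);
  arma::mat Y(hw * n, cout, arma::fill::zeros);
  for (arma::uword j = 0; j < 9; ++j) {
    arma::uvec rows = arma::regspace<arma::uvec>(0, cin - 1) * 9 + j;
    arma::mat g = gatherOffset(P, nbr.col(j) - 1, hw, n, cin);
    Y += g * W.rows(rows);
  }
  Y.each_row() += b.t();
  arma::cube out(Y.memptr(), hw, n, cout);
  return out;
}

// [[Rcpp::export(name = ".convBackwardCpp")]]
List convBackwardCpp(const arma::cube& A, const arma::cube& dOut,
    const arma::mat& W, const arma::umat& nbr, const arma::uvec& padPos,
    int pp, bool needInput) {
  arma::uword hw = A.n_rows, n = A.n_cols, cin = A.n_slices;
  arma::uword cout = W.n_cols;
  arma::cube P = padCube(A, padPos - 1, (arma::uword)pp);
  arma::mat dY(const_cast<double*>(dOut.memptr()), hw * n, cout, false);
  arma::mat dW(9 * cin, cout);
  arma::cube dP;
  if (needInput) dP.zeros(pp, n, cin);
  for (arma::uword j = 0; j < 9; ++j) {
    arma::uvec rows = arma::regspace<arma::uvec>(0, cin - 1) * 9 + j;
    arma::uvec nbrj = nbr.col(j) - 1;
    arma::mat g = gatherOffset(P, nbrj, hw, n, cin);
    dW.rows(rows) = g.t() * dY;
    if (needInput) {
      arma::mat dPj = dY * W.rows(rows).t();   // hw*n x cin
      for (arma::uword c = 0; c < cin; ++c)
        for (arma::uword i = 0; i < n; ++i) {
          double* dst = dP.slice(c).colptr(i);
          const double* src = dPj.colptr(c) + i * hw;
          for (arma::uword p = 0; p < hw; ++p) dst[nbrj[p]] += src[p];
        }
    }
  }
  arma::vec db = arma::sum(dY, 0).t();
  List res = List::create(_["dW"] = dW, _["db"] = db);
  if (needInput) {
    arma::cube dA(hw, n, cin);
    arma::uvec pad0 = padPos - 1;
    for (arma::uword c = 0; c < cin; ++c)
      for (arma::uword i = 0; i < n; ++i) {
        double* dst = dA.slice(c).colptr(i);
        const double* src = dP.slice(c).colptr(i);
        for (arma::uword p = 0; p < hw; ++p) dst[p] = src[pad0[p]];
      }
    res["dA"] = dA;
  }
  return res;
}

// [[Rcpp::export(name = ".poolForwardCpp")]]
List poolForwardCpp(const arma::cube& A, const arma::umat& idx) {
  arma::uword hw2 = idx.n_rows, n = A.n_cols, cc = A.n_slices;
  arma::cube out(hw2, n, cc);
  arma::cube amax(hw2, n, cc);
  for (arma::uword c = 0; c < cc; ++c)
    for (arma::uword i = 0; i < n; ++i) {
      const double* src = A.slice(c).colptr(i);
      double* dst = out.slice(c).colptr(i);
      double* am = amax.slice(c).colptr(i);
      for (arma::uword p = 0; p < hw2; ++p) {
        double best = src[idx(p, 0) - 1];
        arma::uword bk = 0;
        for (arma::uword k = 1; k < 4; ++k) {
          double v = src[idx(p, k) - 1];
          if (v > best) { best = v; bk = k; }
        }
        dst[p] = best;
        am[p] = bk + 1;
      }
    }
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// [[Rcpp::export(name = ".poolBackwardCpp")]]
arma::cube poolBackwardCpp(const arma::cube& dOut, const arma::cube& amax,
    const arma::umat& idx, int hwIn) {
  arma::uword hw2 = idx.n_rows, n = dOut.n_cols, cc = dOut.n_slices;
  arma::cube dA(hwIn, n, cc, arma::fill::zeros);
  for (arma::uword c = 0; c < cc; ++c)
    for (arma::uword i = 0; i < n; ++i) {
      const double* src = dOut.slice(c).colptr(i);
      const double* am = amax.slice(c).colptr(i);
      double* dst = dA.slice(c).colptr(i);
      for (arma::uword p = 0; p < hw2; ++p)
        dst[idx(p, (arma::uword)am[p] - 1) - 1] += src[p];
    }
  return dA;
}
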
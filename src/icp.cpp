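// Similarity-transform ICP inner loop: closest-point pairing against a
// fixed target surface (grid built once) alternated with Umeyama fits.
#include <RcppArmadillo.h>
#include "trigrid.h"
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using ssmesh::Vec3;
using ssmesh::TriGrid;

// least-squares similarity fit X -> Y (rows paired), det(R) = +1
static bool umeyama(const arma::mat& X, const arma::mat& Y, bool allowScale,
                    arma::mat33& R, double& s, arma::vec3& t) {
  arma::rowvec mx = arma::mean(X, 0), my = arma::mean(Y, 0);
  arma::mat Xc = X.each_row() - mx, Yc = Y.each_row() - my;
  arma::mat S = (Yc.t() * Xc) / (double)X.n_rows;
  arma::mat U, V;
  arma::vec d;
  if (!arma::svd(U, d, V, S)) return false;
  double sgn = arma::det(U * V.t()) < 0 ? -1.0 : 1.0;
  arma::vec3 D = {1.0, 1.0, sgn};
  R = U * arma::diagmat(D) * V.t();
  if (allowScale) {
    double varx = arma::accu(Xc % Xc) / (double)X.n_rows;
    if (varx <= 0) return false;
    s = arma::dot(d, D) / varx;
    if (s <= 0) return false;
  } else {
    s = 1.0;
  }
  t = my.t() - s * R * mx.t();
  return true;
}

// [[Rcpp::export(name = ".cpp_icp_similarity")]]
List cpp_icp_similarity(NumericMatrix Src, NumericMatrix Vt, IntegerMatrix Ft,
                        bool allow_scaling, int max_iterations, double tol,
                        double max_dist, NumericMatrix R0, double s0,
                        NumericVector t0) {
  int nT = Ft.nrow();
  std::vector<Vec3> Vtgt(Vt.nrow());
  for (int i = 0; i < Vt.nrow(); ++i) Vtgt[i] = Vec3(Vt(i, 0), Vt(i, 1), Vt(i, 2));
  std::vector<int> Ftgt(3 * nT);
  for (int f = 0; f < nT; ++f) {
    Ftgt[3 * f] = Ft(f, 0); Ftgt[3 * f + 1] = Ft(f, 1); Ftgt[3 * f + 2] = Ft(f, 2);
  }
  TriGrid grid;
  grid.build(Vtgt, Ftgt);

  int m = Src.nrow();
  arma::mat X(m, 3);
  for (int i = 0; i < m; ++i) { X(i, 0) = Src(i, 0); X(i, 1) = Src(i, 1); X(i, 2) = Src(i, 2); }

  arma::mat33 R;
  for (int i = 0; i < 3; ++i) for (int j = 0; j < 3; ++j) R(i, j) = R0(i, j);
  double s = s0;
  arma::vec3 t = {t0[0], t0[1], t0[2]};

  arma::mat Y(m, 3);
  arma::vec dist(m);
  double rms = R_PosInf, rms_prev = R_PosInf;
  int it = 0, nValid = m;
  std::vector<double> rms_trace;
  for (it = 1; it <= max_iterations; ++it) {
    arma::mat Xt = s * X * R.t();
    Xt.each_row() += t.t();
    for (int i = 0; i < m; ++i) {
      Vec3 q(Xt(i, 0), Xt(i, 1), Xt(i, 2)), cp;
      grid.query(q, cp);
      Y(i, 0) = cp.x; Y(i, 1) = cp.y; Y(i, 2) = cp.z;
      double dx = cp.x - Xt(i, 0), dy = cp.y - Xt(i, 1), dz = cp.z - Xt(i, 2);
      dist(i) = std::sqrt(dx * dx + dy * dy + dz * dz);
    }
    arma::uvec keep = arma::find(dist <= max_dist);
    nValid = (int)keep.n_elem;
    if (nValid < 3) return List::create(_["ok"] = false, _["n_valid"] = nValid);
    rms = std::sqrt(arma::accu(arma::square(dist(keep))) / nValid);
    rms_trace.push_back(rms);
    arma::mat33 Rn;
    double sn;
    arma::vec3 tn;
    if (!umeyama(X.rows(keep), Y.rows(keep), allow_scaling, Rn, sn, tn))
      return List::create(_["ok"] = false, _["n_valid"] = nValid);
    R = Rn; s = sn; t = tn;
    if (std::abs(rms_prev - rms) < tol) break;
    rms_prev = rms;
    if (it % 50 == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix Rout(3, 3);
  for (int i = 0; i < 3; ++i) for (int j = 0; j < 3; ++j) Rout(i, j) = R(i, j);
  return List::create(_["ok"] = true, _["rotation"] = Rout, _["scale"] = s,
                      _["translation"] = NumericVector::create(t(0), t(1), t(2)),
                      _["rms"] = rms, _["iterations"] = std::min(it, max_iterations),
                      _["n_valid"] = nValid, _["rms_trace"] = wrap(rms_trace));
}
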
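// R entry point for closest-point-on-surface queries.
#include "trigrid.h"
using namespace Rcpp;
using namespace ssmesh;

static void fillMesh(const NumericMatrix& Vm, const IntegerMatrix& Fm,
                     std::vector<Vec3>& V, std::vector<int>& F) {
  int nV = Vm.nrow(), nF = Fm.nrow();
  V.resize(nV);
  for (int i = 0; i < nV; ++i) V[i] = Vec3(Vm(i, 0), Vm(i, 1), Vm(i, 2));
  F.resize(3 * nF);
  for (int f = 0; f < nF; ++f) {
    F[3 * f] = Fm(f, 0); F[3 * f + 1] = Fm(f, 1); F[3 * f + 2] = Fm(f, 2);
  }
}

static List queryGrid(const TriGrid& grid, const NumericMatrix& Q) {
  int n = Q.nrow();
  NumericMatrix P(n, 3);
  NumericVector dist(n);
  IntegerVector face(n);
  for (int i = 0; i < n; ++i) {
    Vec3 q(Q(i, 0), Q(i, 1), Q(i, 2)), cp;
    int f = grid.query(q, cp);
    P(i, 0) = cp.x; P(i, 1) = cp.y; P(i, 2) = cp.z;
    dist[i] = std::sqrt(norm2(cp - q));
    face[i] = f + 1;  // 1-based for R
  }
  return List::create(_["points"] = P, _["dist"] = dist, _["face"] = face);
}

// [[Rcpp::export(name = ".cpp_closest_point")]]
List cpp_closest_point(NumericMatrix V, IntegerMatrix F, NumericMatrix Q) {
  std::vector<Vec3> Vv; std::vector<int> Fv;
  fillMesh(V, F, Vv, Fv);
  TriGrid grid;
  grid.build(Vv, Fv);
  return queryGrid(grid, Q);
}

// persistent spatial index for repeated queries against a fixed surface
// [[Rcpp::export(name = ".cpp_grid_build")]]
SEXP cpp_grid_build(NumericMatrix V, IntegerMatrix F) {
  std::vector<Vec3> Vv; std::vector<int> Fv;
  fillMesh(V, F, Vv, Fv);
  XPtr<TriGrid> ptr(new TriGrid(), true);
  ptr->build(Vv, Fv);
  return ptr;
}

// [[Rcpp::export(name = ".cpp_grid_query")]]
List cpp_grid_query(SEXP grid_ptr, NumericMatrix Q) {
  XPtr<TriGrid> ptr(grid_ptr);
  return queryGrid(*ptr, Q);
}
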
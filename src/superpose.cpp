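// Exhaustive correspondence search for the site-to-reference superposition.
//
// The metal sits at the origin. For a correspondence c mapping partner i to
// reference vertex c(i), the reference vertex is radially scaled to the
// observed metal-partner distance d_i and the proper rotation minimizing the
// summed squared deviation is found by Kabsch/SVD. The minimum over all
// injective correspondences is returned.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static double kabsch_err(const arma::mat& P, const arma::mat& Q,
                         double sumP2, double sumQ2) {
  arma::mat C = Q.t() * P; // 3x3
  arma::mat U, V;
  arma::vec s;
  if (!arma::svd(U, s, V, C)) return arma::datum::inf;
  double sign = arma::det(V * U.t()) < 0 ? -1.0 : 1.0;
  double tr = s(0) + s(1) + sign * s(2);
  return sumP2 + sumQ2 - 2.0 * tr;
}

// [[Rcpp::export]]
List cpp_best_superposition(const arma::mat& P, const arma::vec& d,
                            const arma::mat& V, const IntegerMatrix& maps) {
  const int n = P.n_rows;
  const int m = maps.nrow();
  const double sumP2 = arma::accu(P % P);
  const double sumQ2 = arma::accu(d % d);
  double best = arma::datum::inf;
  int best_row = -1;
  arma::mat Q(n, 3);
  for (int r = 0; r < m; ++r) {
    for (int i = 0; i < n; ++i) {
      const int j = maps(r, i) - 1;
      Q.row(i) = d(i) * V.row(j);
    }
    double err = kabsch_err(P, Q, sumP2, sumQ2);
    if (err < best) {
      best = err;
      best_row = r;
    }
  }
  // recompute the rotation for the winning correspondence
  for (int i = 0; i < n; ++i) {
    const int j = maps(best_row, i) - 1;
    Q.row(i) = d(i) * V.row(j);
  }
  arma::mat C = Q.t() * P;
  arma::mat U, Vm;
  arma::vec s;
  arma::svd(U, s, Vm, C);
  arma::mat D = arma::eye(3, 3);
  if (arma::det(Vm * U.t()) < 0) D(2, 2) = -1.0;
  arma::mat R = Vm * D * U.t();
  double rmsd = std::sqrt(std::max(0.0, best) / n);
  return List::create(_["rmsd"] = rmsd,
                      _["map"] = maps(best_row, _),
                      _["rotation"] = R);
}
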
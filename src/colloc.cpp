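// Exact per-element solve of the collocation equations of the reduced
// extracellular model. The right-hand side S_e*K*u(t)*(q_bio' x) (+ optional
// dilution term) is linear in the state, so for fixed flux profiles the
// cubic-Lagrange / right-Radau collocation equations of each finite element
// form a square linear system; elements chain through the shared border
// coefficient. This is the inner kernel of every estimation subproblem.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// borders: element borders (n_el + 1)
// Dm:      3 x 4 Lagrange differentiation matrix, column 0 = element start
// W:       n_x x (3 * n_el) values of S_e*K*u at the interior Radau nodes
// x0:      initial state
// bio_idx: 1-based index of the biomass entry of the state
// dil:     per-element dilution rate (0 for batch)
// x_in:    feed concentration vector
// [[Rcpp::export]]
Rcpp::List solve_colloc_states(const arma::vec& borders, const arma::mat& Dm,
                               const arma::mat& W, const arma::vec& x0,
                               const int bio_idx, const arma::vec& dil,
                               const arma::vec& x_in) {
  const int nel = borders.n_elem - 1;
  const int nx = x0.n_elem;
  const int bi = bio_idx - 1;
  arma::mat Xb(nx, nel + 1);
  arma::mat Xn(nx, 3 * nel);
  Xb.col(0) = x0;

  arma::mat M(3 * nx, 3 * nx);
  arma::vec rhs(3 * nx);
  for (int e = 0; e < nel; ++e) {
    const double h = borders[e + 1] - borders[e];
    const double De = dil[e];
    M.zeros();
    rhs.zeros();
    const arma::vec xs = Xb.col(e);
    for (int i = 0; i < 3; ++i) {
      for (int s = 0; s < nx; ++s) {
        const int r = i * nx + s;
        for (int j = 1; j < 4; ++j) M(r, (j - 1) * nx + s) += Dm(i, j) / h;
        M(r, i * nx + bi) -= W(s, 3 * e + i);
        M(r, i * nx + s) += De;
        rhs(r) = -Dm(i, 0) / h * xs(s) + De * x_in(s);
      }
    }
    arma::vec sol;
    const bool ok = arma::solve(sol, M, rhs, arma::solve_opts::no_approx);
    if (!ok) Rcpp::stop("singular collocation system in element %d", e + 1);
    for (int i = 0; i < 3; ++i)
      Xn.col(3 * e + i) = sol.subvec(i * nx, (i + 1) * nx - 1);
    Xb.col(e + 1) = Xn.col(3 * e + 2);
  }
  return Rcpp::List::create(Rcpp::Named("borders") = Xb,
                            Rcpp::Named("nodes") = Xn);
}
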
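// Non-negative lasso coordinate descent and dictionary column updates.
// These are the inner loops of the sparse dictionary-learning harmoniser;
// everything else stays in R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// One cyclic sweep over the coordinates in `which`; returns max |delta|.
static double cd_sweep(const mat& G, const vec& gdiag, const vec& c,
                       double lambda, vec& a, vec& Ga, const uvec& which) {
  double max_delta = 0.0;
  for (uword k = 0; k < which.n_elem; ++k) {
    uword j = which(k);
    if (gdiag(j) <= 0) continue;
    double raw = c(j) - (Ga(j) - gdiag(j) * a(j)) - lambda;
    double aj = raw > 0 ? raw / gdiag(j) : 0.0;
    double delta = aj - a(j);
    if (delta != 0.0) {
      Ga += delta * G.col(j);
      a(j) = aj;
      double ad = std::abs(delta);
      if (ad > max_delta) max_delta = ad;
    }
  }
  return max_delta;
}

// Solve, per column x of X:  min_a 0.5 ||x - D a||^2 + lambda * sum(a),
// s.t. a >= 0, by coordinate descent with an active-set strategy: full
// sweeps alternate with sweeps restricted to the current support until a
// full sweep changes nothing. Columns of D need not be unit norm. An
// optional warm start `init` (p x N) guarantees the objective never
// exceeds its value at the initial codes.
// [[Rcpp::export(name = ".cpp_nnlasso")]]
arma::mat cpp_nnlasso(const arma::mat& D, const arma::mat& X, double lambda,
                      int max_sweeps = 200, double tol = 1e-7,
                      Rcpp::Nullable<Rcpp::NumericMatrix> init = R_NilValue,
                      Rcpp::Nullable<Rcpp::NumericMatrix> gram =
                          R_NilValue) {
  const uword p = D.n_cols, N = X.n_cols;
  mat G = gram.isNotNull() ? Rcpp::as<mat>(gram.get())
                           : mat(D.t() * D); // p x p Gram
  mat C = D.t() * X;            // p x N correlations
  vec gdiag = G.diag();
  mat A(p, N, fill::zeros);
  bool warm = init.isNotNull();
  mat A0;
  if (warm) A0 = Rcpp::as<mat>(init.get());
  uvec all_idx = regspace<uvec>(0, p - 1);
  for (uword n = 0; n < N; ++n) {
    vec a(p, fill::zeros);
    vec Ga(p, fill::zeros);
    if (warm) {
      a = A0.col(n);
      if (any(a != 0)) Ga = G * a;
    }
    const vec c = C.col(n);
    int sweeps = 0;
    while (sweeps < max_sweeps) {
      double d_full = cd_sweep(G, gdiag, c, lambda, a, Ga, all_idx);
      ++sweeps;
      double scale = std::max(1.0, a.max());
      if (d_full <= tol * scale) break;
      // restricted sweeps over the current support
      while (sweeps < max_sweeps) {
        uvec act = find(a > 0);
        if (act.n_elem == 0) break;
        double d_act = cd_sweep(G, gdiag, c, lambda, a, Ga, act);
        ++sweeps;
        if (d_act <= tol * std::max(1.0, a.max())) break;
      }
    }
    A.col(n) = a;
  }
  return A;
}

// Debiasing refit: non-negative least squares restricted to the support
// of each code column (coordinate descent at lambda = 0), removing the
// lasso shrinkage bias while keeping the selected atoms.
// [[Rcpp::export(name = ".cpp_nnls_refit")]]
arma::mat cpp_nnls_refit(const arma::mat& D, const arma::mat& X,
                         const arma::mat& A, int max_sweeps = 50,
                         double tol = 1e-9,
                         Rcpp::Nullable<Rcpp::NumericMatrix> gram =
                             R_NilValue) {
  const uword N = X.n_cols;
  mat G = gram.isNotNull() ? Rcpp::as<mat>(gram.get())
                           : mat(D.t() * D);
  mat C = D.t() * X;
  vec gdiag = G.diag();
  mat A2 = A;
  for (uword n = 0; n < N; ++n) {
    uvec supp = find(A.col(n) > 0);
    if (supp.n_elem == 0) continue;
    vec a = A2.col(n);
    vec Ga = G * a;
    const vec c = C.col(n);
    for (int sweep = 0; sweep < max_sweeps; ++sweep) {
      double d = cd_sweep(G, gdiag, c, 0.0, a, Ga, supp);
      if (d <= tol * std::max(1.0, a.max())) break;
    }
    A2.col(n) = a;
  }
  return A2;
}

// Column updates from accumulated sufficient statistics Acc = sum a a',
// Bcc = sum x a' over all batches seen so far (online dictionary
// learning): the blockwise-optimal unit-norm direction for atom j is
// (Bcc_j - D Acc_j + d_j Acc_jj) normalised. Atoms with ~zero accumulated
// usage are reported as dead (1-based indices).
// [[Rcpp::export(name = ".cpp_dict_update_stats")]]
Rcpp::List cpp_dict_update_stats(arma::mat D, const arma::mat& Acc,
                                 const arma::mat& Bcc) {
  const uword p = D.n_cols;
  std::vector<int> dead;
  for (uword j = 0; j < p; ++j) {
    double usage = Acc(j, j);
    if (usage <= 1e-12) {
      dead.push_back((int)j + 1);
      continue;
    }
    vec u = Bcc.col(j) - D * Acc.col(j) + D.col(j) * usage;
    double nu = norm(u);
    if (nu > 0) D.col(j) = u / nu;
  }
  return Rcpp::List::create(Rcpp::Named("D") = D,
                            Rcpp::Named("dead") = dead);
}

// One pass of blockwise-optimal unit-norm column updates at fixed codes:
// for each used atom j, d_j <- E_j a_j / ||E_j a_j|| with
// E_j = X - D A + d_j a_j'. Monotonically non-increasing reconstruction
// error. Unused atoms (zero code row) are left untouched; their 1-based
// indices are returned so the caller can re-seed them.
// [[Rcpp::export(name = ".cpp_dict_update")]]
Rcpp::List cpp_dict_update(arma::mat D, const arma::mat& X,
                           const arma::mat& A) {
  const uword p = D.n_cols;
  mat R = X - D * A; // residual
  std::vector<int> dead;
  for (uword j = 0; j < p; ++j) {
    rowvec aj = A.row(j);
    double usage = dot(aj, aj);
    if (usage <= 0) {
      dead.push_back((int)j + 1);
      continue;
    }
    vec u = R * aj.t() + D.col(j) * usage; // E_j * a_j
    double nu = norm(u);
    if (nu > 0) {
      vec d_new = u / nu;
      R += (D.col(j) - d_new) * aj;
      D.col(j) = d_new;
    }
  }
  return Rcpp::List::create(Rcpp::Named("D") = D,
                            Rcpp::Named("dead") = dead);
}
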
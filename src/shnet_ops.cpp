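// Frozen-BN network objective for the deterministic fine-tuning phase.
// With batch-norm statistics frozen, each BN layer is a fixed per-feature
// affine map, so the deployed network is affine -> FC(+ReLU) stacks; this
// computes the mean-squared-error loss and its gradient with respect to
// the FC weights only (the BN affine parameters are redundant with them).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".cpp_mlp_loss_grad")]]
Rcpp::List cpp_mlp_loss_grad(const Rcpp::List& Ws, const Rcpp::List& bs,
                             const Rcpp::List& scales,
                             const Rcpp::List& shifts,
                             const arma::mat& X, const arma::mat& T,
                             bool want_grad = true) {
  const int L = Ws.size();
  std::vector<mat> inputs(L);    // input to each FC layer (post-affine)
  std::vector<mat> zs(L);        // pre-activation outputs
  mat H = X;
  for (int i = 0; i < L; ++i) {
    rowvec sc = Rcpp::as<rowvec>(scales[i]);
    rowvec sh = Rcpp::as<rowvec>(shifts[i]);
    H.each_row() %= sc;
    H.each_row() += sh;
    inputs[i] = H;
    mat W = Rcpp::as<mat>(Ws[i]);
    rowvec b = Rcpp::as<rowvec>(bs[i]);
    mat Z = H * W;
    Z.each_row() += b;
    zs[i] = Z;
    H = (i < L - 1) ? clamp(Z, 0.0, datum::inf) : Z;
  }
  const double n_el = (double)T.n_elem;
  mat diff = H - T;
  double loss = accu(square(diff)) / n_el;
  if (!want_grad) {
    return Rcpp::List::create(Rcpp::Named("loss") = loss);
  }
  Rcpp::List gW(L), gb(L);
  mat dH = 2.0 * diff / n_el;
  for (int i = L - 1; i >= 0; --i) {
    mat dZ = dH;
    if (i < L - 1) dZ %= conv_to<mat>::from(zs[i] > 0);
    gW[i] = inputs[i].t() * dZ;
    gb[i] = sum(dZ, 0);
    if (i > 0) {
      mat W = Rcpp::as<mat>(Ws[i]);
      dH = dZ * W.t();
      rowvec sc = Rcpp::as<rowvec>(scales[i]);
      dH.each_row() %= sc; // back through the fixed affine
    }
  }
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}
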
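#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Bulk Gaussian matrix draw for the simulator's noise streams.  Uses R's
// RNG (via RcppArmadillo), so results are reproducible under set.seed and
// a single draw is much faster than matrix(rnorm(...)).
// [[Rcpp::export]]
arma::mat cpp_randn(const int nr, const int nc, const double sd) {
  arma::mat out(nr, nc, arma::fill::randn);
  return sd * out;
}
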
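// Single-chain single-site Gibbs sampler for a Potts-like model with
// same-state bonus couplings: p(x) ~ exp(sum_i h_i(x_i) +
// sum_{(i,j) in E} beta_ij [x_i == x_j]). Uses R's RNG so that draws are
// reproducible under set.seed().

#include <RcppArmadillo.h>

// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
Rcpp::IntegerMatrix gibbs_sample_cpp(int L, int q, const arma::mat& h,
                                     const arma::ivec& pair_i,
                                     const arma::ivec& pair_j,
                                     const arma::vec& beta,
                                     int M, int burn_in, int thin) {
  // adjacency: for each site, list of (partner, coupling strength)
  std::vector<std::vector<std::pair<int, double>>> nb(L);
  for (arma::uword e = 0; e < pair_i.n_elem; ++e) {
    const int a = pair_i(e) - 1, b = pair_j(e) - 1;  // 1-based in R
    nb[a].push_back({b, beta(e)});
    nb[b].push_back({a, beta(e)});
  }

  Rcpp::IntegerMatrix out(M, L);
  std::vector<int> x(L);
  std::vector<double> logp(q), prob(q);

  for (int i = 0; i < L; ++i) {
    x[i] = std::min(q - 1, int(R::unif_rand() * q));
  }

  auto sweep = [&]() {
    for (int i = 0; i < L; ++i) {
      double mx = -1e300;
      for (int a = 0; a < q; ++a) logp[a] = h(i, a);
      for (const auto& e : nb[i]) logp[x[e.first]] += e.second;
      for (int a = 0; a < q; ++a) if (logp[a] > mx) mx = logp[a];
      double tot = 0.0;
      for (int a = 0; a < q; ++a) { prob[a] = std::exp(logp[a] - mx); tot += prob[a]; }
      const double u = R::unif_rand() * tot;
      double acc = 0.0;
      int pick = q - 1;
      for (int a = 0; a < q; ++a) {
        acc += prob[a];
        if (u < acc) { pick = a; break; }
      }
      x[i] = pick;
    }
  };

  for (int s = 0; s < burn_in; ++s) sweep();
  for (int m = 0; m < M; ++m) {
    for (int s = 0; s < thin; ++s) sweep();
    for (int i = 0; i < L; ++i) out(m, i) = x[i];
  }
  return out;
}
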
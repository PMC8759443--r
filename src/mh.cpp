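#include <Rcpp.h>
using namespace Rcpp;

// Metropolis sampler for the latent log-ratio vector of one sample under the
// logistic-normal multinomial model.
//
// Target (up to a constant):
//   log f(y | w, eta) = sum_q w_q y_q - m log(sum_q exp(y_q) + 1)
//                       - 0.5 (y - mu)' Omega (y - mu)
// where the sums run over the Q-1 non-base taxa, m is the total count
// (including the base taxon) and Omega is the precision used for the latent
// Gaussian (a generalized inverse or regularized inverse of Sigma).
//
// proposal = "componentwise" (joint = false): one retained draw is the state
// after a full systematic sweep of single-coordinate N(y_q, v) proposals;
// the acceptance rate is the fraction of accepted coordinate proposals after
// burn-in. joint = true follows the all-coordinates-at-once N(y, vI)
// proposal; the acceptance rate is then the per-draw acceptance fraction.
//
// Uses R's RNG stream, so set.seed() in R makes the chain reproducible.

static double log_denominator(const std::vector<double>& y) {
  // log(sum(exp(y)) + 1), max-shifted (the implicit base coordinate is 0)
  double mx = 0.0;
  for (double yi : y) if (yi > mx) mx = yi;
  double s = std::exp(-mx); // the "+1" term
  for (double yi : y) s += std::exp(yi - mx);
  return mx + std::log(s);
}

// [[Rcpp::export(name = ".mh_chain_cpp")]]
List mh_chain_cpp(NumericVector w_nb, double m, NumericVector y0,
                  NumericVector mu, NumericMatrix omega,
                  double v, int burn, int r_draws, bool joint) {
  const int K = y0.size();
  if (w_nb.size() != K || mu.size() != K || omega.nrow() != K ||
      omega.ncol() != K) {
    stop("dimension mismatch in MH sampler inputs");
  }
  const double sd = std::sqrt(v);
  std::vector<double> y(y0.begin(), y0.end());
  NumericMatrix draws(r_draws, K);
  long long accepted = 0, proposed = 0;

  RNGScope scope;

  if (joint) {
    // full-vector spherical proposal, as printed in the model description
    std::vector<double> ystar(K);
    double cur_mult = 0.0;
    for (int q = 0; q < K; ++q) cur_mult += w_nb[q] * y[q];
    cur_mult -= m * log_denominator(y);
    auto gauss = [&](const std::vector<double>& yy) {
      double quad = 0.0;
      for (int a = 0; a < K; ++a) {
        double row = 0.0;
        for (int b = 0; b < K; ++b) row += omega(a, b) * (yy[b] - mu[b]);
        quad += (yy[a] - mu[a]) * row;
      }
      return -0.5 * quad;
    };
    double cur = cur_mult + gauss(y);
    for (int r = 0; r < burn + r_draws; ++r) {
      for (int q = 0; q < K; ++q) ystar[q] = y[q] + R::rnorm(0.0, sd);
      double prop_mult = 0.0;
      for (int q = 0; q < K; ++q) prop_mult += w_nb[q] * ystar[q];
      prop_mult -= m * log_denominator(ystar);
      double prop = prop_mult + gauss(ystar);
      bool post_burn = r >= burn;
      if (post_burn) ++proposed;
      if (std::log(R::runif(0.0, 1.0)) < prop - cur) {
        y = ystar;
        cur = prop;
        if (post_burn) ++accepted;
      }
      if (post_burn) {
        for (int q = 0; q < K; ++q) draws(r - burn, q) = y[q];
      }
    }
  } else {
    // coordinate-wise sweeps; maintain g = Omega (y - mu) and the softmax
    // denominator incrementally, refreshing once per sweep against drift
    std::vector<double> g(K, 0.0);
    for (int a = 0; a < K; ++a) {
      double row = 0.0;
      for (int b = 0; b < K; ++b) row += omega(a, b) * (y[b] - mu[b]);
      g[a] = row;
    }
    for (int r = 0; r < burn + r_draws; ++r) {
      // refresh the denominator exactly once per sweep (max-shifted)
      double mx = 0.0;
      for (int q = 0; q < K; ++q) if (y[q] > mx) mx = y[q];
      double S = std::exp(-mx);
      for (int q = 0; q < K; ++q) S += std::exp(y[q] - mx);
      bool post_burn = r >= burn;
      for (int q = 0; q < K; ++q) {
        double delta = R::rnorm(0.0, sd);
        double eyq = std::exp(y[q] - mx);
        double eyq_new = std::exp(y[q] + delta - mx);
        double S_new = S - eyq + eyq_new;
        if (!(S_new > 0.0) || !std::isfinite(S_new)) continue; // overflow guard
        double d_mult = w_nb[q] * delta - m * (std::log(S_new) - std::log(S));
        double d_gauss = -(delta * g[q] + 0.5 * delta * delta * omega(q, q));
        if (post_burn) ++proposed;
        if (std::log(R::runif(0.0, 1.0)) < d_mult + d_gauss) {
          y[q] += delta;
          S = S_new;
          for (int a = 0; a < K; ++a) g[a] += delta * omega(a, q);
          if (post_burn) ++accepted;
        }
      }
      if (post_burn) {
        for (int q = 0; q < K; ++q) draws(r - burn, q) = y[q];
      }
    }
  }

  double rate = proposed > 0 ? (double)accepted / (double)proposed : NA_REAL;
  return List::create(_["draws"] = draws, _["acceptance_rate"] = rate);
}
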
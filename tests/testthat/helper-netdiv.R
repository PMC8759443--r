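# Shared fixtures: everything is generated in code at test time.

# a small deterministic two-group dataset from the generative model
small_sim <- function(n = 12, Q = 10, seed = 101, M = NULL,
                      network_strength = 0.5, depth_range = c(2000, 5000)) {
  design <- design_from_template(n = n, Q = Q, M = M,
                                 network_strength = network_strength,
                                 depth_range = depth_range, seed = seed)
  simulate_dataset(design, seed = seed + 1)
}

# short-chain configurations to keep unit tests fast
fast_mh <- function(...) mh_config(burn = 100, r_draws = 100, ...)
fast_em <- function(...) em_config(n_iter = 2, ...)

# random strictly positive composition
rcomp <- function(Q) {
  x <- stats::rgamma(Q, shape = 0.7) + 1e-6
  x / sum(x)
}

# numerical-quadrature posterior mean for the Q = 2 toy model (scalar y):
# target ∝ exp(w1 y - m log(e^y + 1) - (y - mu)^2 / (2 s2))
toy_posterior_mean <- function(w1, m, mu, s2) {
  logpost <- function(y) w1 * y - m * log1p(exp(y)) - (y - mu)^2 / (2 * s2)
  grid <- seq(mu - 15, mu + 15, length.out = 20001)
  lp <- logpost(grid)
  wts <- exp(lp - max(lp))
  sum(grid * wts) / sum(wts)
}

# batch-means Monte-Carlo standard error of a chain's mean
mcse_batch <- function(x, n_batches = 25) {
  bs <- floor(length(x) / n_batches)
  means <- vapply(seq_len(n_batches),
                  function(b) mean(x[((b - 1) * bs + 1):(b * bs)]),
                  numeric(1))
  stats::sd(means) / sqrt(n_batches)
}
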
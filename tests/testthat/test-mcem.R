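test_that("multinomial log-likelihood matches the closed form and is not shift-invariant", {
  expect_equal(multinomial_loglik_y(c(1, 0, 1), c(0, 0), base = 3),
               -2 * log(3))
  # brute-force evaluation on random instances
  set.seed(23)
  for (i in 1:10) {
    w <- rmultinom(1, 50, rcomp(5))[, 1] + 0.5
    y <- rnorm(4)
    brute <- sum(w[-5] * y) - sum(w) * log(sum(exp(y)) + 1)
    expect_equal(multinomial_loglik_y(w, y, base = 5), brute)
    # a softmax-only implementation would be shift-invariant; this one is not
    expect_false(isTRUE(all.equal(multinomial_loglik_y(w, y + 1, base = 5),
                                  multinomial_loglik_y(w, y, base = 5))))
  }
  # stable for large log-ratios where exp would overflow
  expect_true(is.finite(multinomial_loglik_y(c(5, 1, 3), c(800, -800), base = 3)))
  expect_error(multinomial_loglik_y(c(1, 2, 3), c(0, 0, 0), base = 3), "length")
})

test_that("gaussian log-likelihood handles full-rank and singular covariances", {
  S <- matrix(c(2, 0.5, 0.5, 1), 2)
  mu <- c(1, -1)
  expect_equal(gaussian_loglik(mu, mu, S), -0.5 * log(det(S)))
  expect_equal(gaussian_loglik(c(1, 0), c(0, 0), diag(2)), -0.5)
  # quadratic form against an explicit solve() oracle
  y <- c(0.3, 2)
  oracle_full <- -0.5 * log(det(S)) -
    0.5 * as.numeric(t(y - mu) %*% solve(S) %*% (y - mu))
  expect_equal(gaussian_loglik(y, mu, S), oracle_full)
  # singular covariance, displacement inside the column space:
  v <- c(1, 2)
  S1 <- tcrossprod(v) # rank 1
  eig <- eigen(S1, symmetric = TRUE)
  lam <- eig$values[1]
  disp <- 0.7 * v
  oracle <- -0.5 * log(lam) - 0.5 * sum(crossprod(eig$vectors[, 1], disp)^2) / lam
  got <- gaussian_loglik(mu + disp, mu, S1)
  expect_true(is.finite(got))
  expect_equal(got, oracle)
})

test_that("MH sampler is deterministic given seed and has valid acceptance", {
  w <- c(30, 10, 5, 55) + 0.5
  mu <- rep(0, 3)
  omega <- diag(3)
  a <- mh_sample(w, mu, omega, base = 4, mh_config(burn = 50, r_draws = 80),
                 seed = 9)
  b <- mh_sample(w, mu, omega, base = 4, mh_config(burn = 50, r_draws = 80),
                 seed = 9)
  expect_identical(a$draws, b$draws)
  expect_true(a$acceptance_rate >= 0 && a$acceptance_rate <= 1)
  expect_equal(dim(a$draws), c(80L, 3L))
  # joint proposal variant obeys the same contract
  d <- mh_sample(w, mu, omega, base = 4,
                 mh_config(burn = 50, r_draws = 80, proposal = "joint"),
                 seed = 9)
  expect_equal(dim(d$draws), c(80L, 3L))
  expect_true(d$acceptance_rate >= 0 && d$acceptance_rate <= 1)
  expect_error(mh_sample(c(1, 0, 2), mu[1:2], diag(2), base = 3,
                         mh_config()), "strictly positive")
})

test_that("MH chain matches quadrature posterior mean on the scalar toy model", {
  # Q = 2: scalar latent log-ratio; both proposal flavours
  w1 <- 12; w2 <- 8
  w <- c(w1, w2) + 0.5
  mu <- 0.4; s2 <- 2
  truth <- toy_posterior_mean(w[1], sum(w), mu, s2)
  for (prop in c("componentwise", "joint")) {
    res <- mh_sample(w, mu, matrix(1 / s2), base = 2,
                     mh_config(v = 0.5, burn = 1000, r_draws = 20000,
                               proposal = prop), seed = 17)
    chain <- res$draws[, 1]
    se <- mcse_batch(chain)
    expect_lt(abs(mean(chain) - truth), 3 * se + 1e-8)
  }
})

test_that("e_step is order-independent and reduces to mh_sample at n = 1", {
  sim <- small_sim(n = 4, Q = 6, seed = 41)
  W_rho <- perturb(sim$W, 0.5)
  X <- sim$design$X
  gamma <- matrix(0, 2, 5)
  omega <- diag(5)
  es <- e_step(W_rho, X, gamma, omega, base = 6,
               mh_config(burn = 30, r_draws = 40), seed = 3)
  expect_length(es$draws, 4)
  expect_true(all(es$acceptance_rates >= 0 & es$acceptance_rates <= 1))
  # permuting the sample order leaves each sample's draws unchanged
  perm <- c(3, 1, 4, 2)
  es_p <- e_step(W_rho[perm, ], X[perm, ], gamma, omega, base = 6,
                 mh_config(burn = 30, r_draws = 40), seed = 3)
  for (k in seq_along(perm)) {
    expect_identical(es_p$draws[[k]], es$draws[[perm[k]]])
  }
})

test_that("m_step equals OLS at R = 1 and a brute-force oracle in general", {
  # two-point OLS: X = (1,1)', Y = (1,3)' -> gamma = 2
  draws <- list(matrix(1, 1, 1), matrix(3, 1, 1))
  ms <- m_step(draws, X = matrix(1, 2, 1), mu_t = matrix(0, 2, 1))
  expect_equal(as.numeric(ms$gamma), 2)

  # all residuals zero -> sigma = 0
  mu_t <- matrix(c(1, 2, 1, 2), 2, 2)
  draws0 <- list(matrix(mu_t[1, ], 3, 2, byrow = TRUE),
                 matrix(mu_t[2, ], 3, 2, byrow = TRUE))
  ms0 <- m_step(draws0, X = matrix(1, 2, 1), mu_t = mu_t)
  expect_equal(ms0$sigma, matrix(0, 2, 2))

  # random small instance vs term-by-term brute force
  set.seed(77)
  n <- 5; p <- 2; K <- 3; R <- 3
  X <- cbind(1, rnorm(n))
  draws <- replicate(n, matrix(rnorm(R * K), R, K), simplify = FALSE)
  mu_t <- matrix(rnorm(n * K), n, K)
  ms <- m_step(draws, X, mu_t)
  gamma_bf <- matrix(0, p, K)
  XtXinv <- solve(t(X) %*% X)
  for (r in seq_len(R)) {
    Yr <- t(vapply(draws, function(d) d[r, ], numeric(K)))
    gamma_bf <- gamma_bf + XtXinv %*% t(X) %*% Yr / R
  }
  sigma_bf <- matrix(0, K, K)
  for (r in seq_len(R)) {
    for (i in seq_len(n)) {
      resid <- draws[[i]][r, ] - mu_t[i, ]
      sigma_bf <- sigma_bf + tcrossprod(resid) / (n * R)
    }
  }
  expect_equal(ms$gamma, gamma_bf, tolerance = 1e-10)
  expect_equal(ms$sigma, sigma_bf, tolerance = 1e-10)
  expect_equal(ms$mu, X %*% gamma_bf, tolerance = 1e-10)

  # updated-mean centering matches brute force with the new mean
  ms2 <- m_step(draws, X, mu_t, center_at_updated_mean = TRUE)
  sigma_bf2 <- matrix(0, K, K)
  mu_new <- X %*% gamma_bf
  for (r in seq_len(R)) {
    for (i in seq_len(n)) {
      resid <- draws[[i]][r, ] - mu_new[i, ]
      sigma_bf2 <- sigma_bf2 + tcrossprod(resid) / (n * R)
    }
  }
  expect_equal(ms2$sigma, sigma_bf2, tolerance = 1e-10)

  # rank-deficient X: generalized inverse, no error
  Xrd <- cbind(1, c(1, 1, 1, 1, 1))
  expect_no_error(m_step(draws, Xrd, mu_t))
})

test_that("estimate_precision implements the three variants", {
  expect_equal(estimate_precision(diag(3), "naive"), diag(3))
  expect_equal(estimate_precision(diag(3), "diagonal"), diag(3))
  expect_equal(estimate_precision(diag(3), "glasso"), diag(3),
               tolerance = 0.15) # penalized: shrunk toward diagonal

  S <- matrix(c(2, 0.8, 0.8, 1), 2)
  expect_equal(estimate_precision(S, "diagonal"), diag(c(0.5, 1)))

  # pseudo-inverse of the rank-1 matrix of ones
  ones <- matrix(1, 2, 2)
  expect_equal(estimate_precision(ones, "naive"), matrix(0.25, 2, 2))
  expect_error(estimate_precision(matrix(c(1, 2, 0, 1), 2), "naive"),
               "symmetric")

  # glasso with strong structure recovers a sparse-ish precision:
  # block covariance with an off-diagonal pair
  set.seed(5)
  Sg <- diag(4); Sg[1, 2] <- Sg[2, 1] <- 0.7
  dat <- rmvnorm_psd(80, numeric(4), Sg)
  P <- estimate_precision(cov(dat), "glasso", data = dat, seed = 2)
  expect_true(abs(P[1, 2]) > abs(P[3, 4])) # true edge stronger than null edge
})

test_that("fit_logratio is deterministic and tracks valid diagnostics", {
  sim <- small_sim(n = 6, Q = 8, seed = 51)
  f1 <- fit_logratio(sim$W, sim$design$X, mh = fast_mh(), em = fast_em(),
                     seed = 13)
  f2 <- fit_logratio(sim$W, sim$design$X, mh = fast_mh(), em = fast_em(),
                     seed = 13)
  expect_identical(f1$gamma, f2$gamma)
  expect_identical(f1$sigma, f2$sigma)
  expect_true(all(f1$trace$mean_acceptance >= 0 &
                    f1$trace$mean_acceptance <= 1))
  # every sigma is symmetric PSD
  ev <- eigen(f1$sigma, symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev) > -1e-10)
  expect_equal(f1$sigma, t(f1$sigma))
  expect_error(fit_logratio(sim$W[1, , drop = FALSE], sim$design$X[1, , drop = FALSE]),
               "single sample")
  expect_warning(fit_logratio(sim$W, cbind(sim$design$X, 0), mh = fast_mh(),
                              em = em_config(n_iter = 1), seed = 1),
                 "all-zero")
})

test_that("fitted compositions approach pooled proportions in the multinomial limit", {
  # Sigma ~ 0, intercept-only: the model collapses to one multinomial
  Q <- 12
  design <- design_from_template(n = 8, Q = Q, group_fraction = 0,
                                 sigma = diag(1e-6, Q - 1),
                                 M = rep(5e4, 8), seed = 61)
  sim <- simulate_dataset(design, seed = 62)
  fit <- fit_logratio(sim$W, base = Q, mh = fast_mh(), em = fast_em(),
                      seed = 63)
  zhat <- fitted_compositions(fit)$z_profile[1, ]
  pooled <- colSums(sim$W) / sum(sim$W)
  expect_lt(max(abs(zhat - pooled)), 0.01) # within 1% per coordinate
})
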
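# Graphical lasso (L1-penalized Gaussian precision estimation) by block
# coordinate descent, with StARS-style stability selection of the penalty.
# Written in-package: no penalized-precision estimator ships with the
# environment this package targets. Intended for the modest latent dimensions
# at which a regularized E-step precision is useful in practice.

# One lasso subproblem: minimize 0.5 b' W11 b - s12' b + lambda ||b||_1
lasso_cd <- function(W11, s12, lambda, beta = NULL, tol = 1e-6,
                     max_iter = 200L) {
  k <- length(s12)
  if (is.null(beta)) beta <- numeric(k)
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(k)) {
      r <- s12[j] - sum(W11[j, -j] * beta[-j])
      bj <- sign(r) * max(abs(r) - lambda, 0) / W11[j, j]
      delta <- max(delta, abs(bj - beta[j]))
      beta[j] <- bj
    }
    if (delta < tol) break
  }
  beta
}

# Full graphical lasso: returns the estimated precision matrix `theta` and
# the regularized covariance `w`.
glasso_fit <- function(S, lambda, tol = 1e-4, max_iter = 50L) {
  K <- nrow(S)
  if (K == 1L) return(list(theta = matrix(1 / (S[1, 1] + lambda), 1, 1),
                           w = S + lambda))
  W <- S + lambda * diag(K)
  B <- matrix(0, K - 1, K)
  off_scale <- mean(abs(S[upper.tri(S)])) + 1e-12
  for (it in seq_len(max_iter)) {
    W_old <- W
    for (j in seq_len(K)) {
      B[, j] <- lasso_cd(W[-j, -j, drop = FALSE], S[-j, j], lambda, B[, j])
      w12 <- W[-j, -j, drop = FALSE] %*% B[, j]
      W[-j, j] <- w12
      W[j, -j] <- w12
    }
    if (mean(abs(W - W_old)) < tol * off_scale) break
  }
  theta <- matrix(0, K, K)
  for (j in seq_len(K)) {
    th22 <- 1 / (W[j, j] - sum(W[-j, j] * B[, j]))
    theta[j, j] <- th22
    theta[-j, j] <- -B[, j] * th22
  }
  theta <- symmetrize(theta)
  list(theta = theta, w = W)
}

glasso_edges <- function(theta, eps = 1e-8) {
  abs(theta[upper.tri(theta)]) > eps
}

# Stability-based penalty selection over a log-spaced path, then a final
# graphical-lasso fit on the full covariance at the selected penalty.
# Instability of an edge at frequency f across subsamples is 2 f (1 - f);
# the selected penalty is the smallest (densest) whose monotonized mean
# instability stays below `threshold` (0.05 by convention).
glasso_stability <- function(sigma, data = NULL, n_lambda = 8L,
                             n_subsample = 12L, threshold = 0.05,
                             seed = 1L) {
  K <- nrow(sigma)
  if (K == 1L) return(matrix(1 / sigma[1, 1], 1, 1))
  if (is.null(data)) {
    # no observations available: draw Gaussian pseudo-observations from sigma
    set.seed(seed)
    data <- rmvnorm_psd(50L, numeric(K), sigma)
  }
  n <- nrow(data)
  b <- max(4L, min(n, ceiling(10 * sqrt(n))))
  # pad above max|offdiag| so the sparsest path point is empty on subsamples too
  lam_max <- 1.5 * max(abs(sigma[upper.tri(sigma)]), diag(sigma) * 0.1, 1e-6)
  lambdas <- sort(exp(seq(log(lam_max), log(lam_max / 100), length.out = n_lambda)),
                  decreasing = TRUE)
  set.seed(seed)
  n_edges <- K * (K - 1) / 2
  freq <- matrix(0, length(lambdas), n_edges)
  for (s in seq_len(n_subsample)) {
    idx <- sample.int(n, b, replace = b >= n)
    Ss <- symmetrize(crossprod(scale(data[idx, , drop = FALSE],
                                     scale = FALSE)) / length(idx))
    for (l in seq_along(lambdas)) {
      th <- glasso_fit(Ss, lambdas[l])$theta
      freq[l, ] <- freq[l, ] + glasso_edges(th)
    }
  }
  freq <- freq / n_subsample
  instab <- rowMeans(2 * freq * (1 - freq))
  instab_mono <- cummax(instab) # lambdas are in decreasing order
  ok <- which(instab_mono <= threshold)
  lambda_sel <- if (length(ok) > 0) lambdas[max(ok)] else lambdas[1]
  glasso_fit(symmetrize(sigma), lambda_sel)$theta
}

# PSD-safe multivariate normal sampler (eigendecomposition square root).
rmvnorm_psd <- function(n, mean, sigma) {
  K <- length(mean)
  eig <- eigen(symmetrize(sigma), symmetric = TRUE)
  if (min(eig$values) < -1e-8 * max(abs(eig$values), 1)) {
    stop("`sigma` is not positive semi-definite", call. = FALSE)
  }
  B <- eig$vectors %*% diag(sqrt(pmax(eig$values, 0)), K)
  E <- matrix(stats::rnorm(n * K), n, K) %*% t(B)
  sweep(E, 2, mean, "+")
}
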
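#' Metropolis-Hastings sampler configuration
#'
#' @param v Proposal variance (step-size tuning parameter). Default `0.01`.
#' @param burn Number of discarded draws (burn-in). Default `500`.
#' @param r_draws Number of retained draws `R`. Default `500`.
#' @param proposal `"componentwise"` (default) updates one coordinate at a
#'   time with `N(y_q, v)` proposals, a full sweep per retained draw;
#'   `"joint"` proposes all coordinates at once from `N(y, vI)`. See the
#'   methods vignette: at realistic sequencing depths the joint proposal with
#'   `v = 0.01` has vanishing acceptance, so coordinate-wise updates are the
#'   practical default.
#' @return An object of class `mh_config`.
#' @export
mh_config <- function(v = 0.01, burn = 500L, r_draws = 500L,
                      proposal = c("componentwise", "joint")) {
  proposal <- match.arg(proposal)
  stopifnot(is.numeric(v), length(v) == 1L, v > 0,
            burn >= 0, r_draws >= 1)
  structure(list(v = v, burn = as.integer(burn),
                 r_draws = as.integer(r_draws), proposal = proposal),
            class = "mh_config")
}

#' EM configuration
#'
#' @param n_iter Number of EM iterations. Six iterations are generally
#'   sufficient for stable estimates at microbiome scale.
#' @param precision_method How the precision (inverse covariance) used in the
#'   E-step is formed from the current covariance estimate: `"naive"`
#'   (Moore-Penrose generalized inverse, the default), `"diagonal"` (inverse
#'   of the diagonal), or `"glasso"` (graphical-lasso regularized inverse
#'   with stability-based penalty selection).
#' @param center_at_updated_mean If `FALSE` (default) the covariance update
#'   centers residuals at the previous iteration's mean, following the
#'   printed update; `TRUE` centers at the freshly updated mean
#'   (standard EM behaviour).
#' @return An object of class `em_config`.
#' @export
em_config <- function(n_iter = 6L,
                      precision_method = c("naive", "diagonal", "glasso"),
                      center_at_updated_mean = FALSE) {
  precision_method <- match.arg(precision_method)
  stopifnot(n_iter >= 1)
  structure(list(n_iter = as.integer(n_iter),
                 precision_method = precision_method,
                 center_at_updated_mean = isTRUE(center_at_updated_mean)),
            class = "em_config")
}

#' Multinomial log-likelihood of counts given latent log-ratios
#'
#' Computes \eqn{\sum_{q \ne d} w_q y_q - m \log(\sum_{q \ne d} e^{y_q} + 1)}
#' with a log-sum-exp-stable reduction, where `m = sum(w)` includes the base
#' taxon. The multinomial coefficient is dropped: it cancels in MH ratios and
#' does not affect maximization. Note the value is not invariant to adding a
#' constant to `y` (the base coordinate is pinned at 0).
#'
#' @param w Count vector of length `Q` (may be perturbed, i.e. non-integer).
#' @param y Log-ratio vector of length `Q - 1`.
#' @param base Index of the base taxon in `w`.
#' @return Log-likelihood up to an additive constant.
#' @export
multinomial_loglik_y <- function(w, y, base) {
  base <- check_base(base, length(w))
  if (length(y) != length(w) - 1L) {
    stop("`y` must have length `length(w) - 1`", call. = FALSE)
  }
  m <- sum(w)
  shift <- max(y, 0)
  log_denom <- shift + log(sum(exp(y - shift)) + exp(-shift))
  sum(w[-base] * y) - m * log_denom
}

#' Gaussian log-density of a log-ratio vector (up to a constant)
#'
#' Computes \eqn{-\tfrac12 \log|\Sigma| - \tfrac12 (y-\mu)^T \Sigma^{-1}
#' (y-\mu)}, omitting the \eqn{2\pi} constant consistently across calls.
#' Singular covariances are handled through the eigendecomposition: the
#' pseudo-determinant (product of nonzero eigenvalues) and the Moore-Penrose
#' generalized inverse are used, so `y - mu` in the column space of `sigma`
#' yields a finite value.
#'
#' @param y,mu Numeric vectors of equal length.
#' @param sigma Symmetric positive semi-definite covariance matrix.
#' @return Log-density up to an additive constant.
#' @export
gaussian_loglik <- function(y, mu, sigma) {
  if (length(y) != length(mu) || length(y) != nrow(sigma) ||
      nrow(sigma) != ncol(sigma)) {
    stop("dimension mismatch between `y`, `mu` and `sigma`", call. = FALSE)
  }
  eig <- eigen(symmetrize(sigma), symmetric = TRUE)
  tol <- length(y) * .Machine$double.eps * max(abs(eig$values), 0)
  keep <- eig$values > tol
  logpdet <- sum(log(eig$values[keep]))
  u <- crossprod(eig$vectors[, keep, drop = FALSE], y - mu)
  quad <- sum(u^2 / eig$values[keep])
  -0.5 * logpdet - 0.5 * quad
}

symmetrize <- function(A) (A + t(A)) / 2

#' Moore-Penrose generalized inverse
#'
#' Symmetric eigendecomposition-based pseudo-inverse. Eigenvalues below
#' `dim * .Machine$double.eps * max(|eigenvalue|)` are treated as zero.
#'
#' @param A Symmetric matrix.
#' @return The generalized inverse of `A`.
#' @keywords internal
pinv <- function(A) {
  eig <- eigen(symmetrize(A), symmetric = TRUE)
  tol <- nrow(A) * .Machine$double.eps * max(abs(eig$values), 0)
  keep <- abs(eig$values) > tol
  if (!any(keep)) return(matrix(0, nrow(A), ncol(A)))
  V <- eig$vectors[, keep, drop = FALSE]
  V %*% (t(V) / eig$values[keep])
}

#' Sample the latent log-ratios of one community
#'
#' Runs a Metropolis chain targeting the conditional distribution of the
#' latent log-ratio vector given observed counts and current parameters.
#' The chain is initialized at the observed log-ratios
#' \eqn{\phi(w / m)} (which requires strictly positive `w`, i.e. perturbed
#' counts), `burn` draws are discarded and `r_draws` retained. Deterministic
#' given `seed`.
#'
#' @param w Strictly positive (perturbed) count vector of length `Q`.
#' @param mu Prior mean of the log-ratios, length `Q - 1`.
#' @param sigma_inv Precision matrix used for the latent Gaussian,
#'   `(Q-1) x (Q-1)` symmetric PSD.
#' @param base Index of the base taxon.
#' @param cfg An [mh_config()].
#' @param seed Optional integer seed (applied via `set.seed`).
#' @param init Optional initial state; defaults to `alr(w / sum(w), base)`.
#' @return A list with `draws` (`r_draws x (Q-1)` matrix) and
#'   `acceptance_rate` (fraction of accepted proposals after burn-in).
#' @export
mh_sample <- function(w, mu, sigma_inv, base, cfg = mh_config(),
                      seed = NULL, init = NULL) {
  base <- check_base(base, length(w))
  if (any(w <= 0)) {
    stop("`w` must be strictly positive; perturb the counts first",
         call. = FALSE)
  }
  m <- sum(w)
  if (is.null(init)) init <- log(w[-base] / w[base])
  if (any(!is.finite(init))) {
    stop("non-finite log-density at initialization", call. = FALSE)
  }
  if (length(mu) != length(init) || nrow(sigma_inv) != length(init)) {
    stop("dimension mismatch between `w`, `mu` and `sigma_inv`", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  res <- .mh_chain_cpp(as.numeric(w[-base]), m, as.numeric(init),
                       as.numeric(mu), as.matrix(sigma_inv),
                       cfg$v, cfg$burn, cfg$r_draws,
                       cfg$proposal == "joint")
  res
}

# deterministic per-chain seed; order-independent across samples and kept
# below 2^31. `i` may be an integer index or a sample label (hashed), so a
# sample keeps its chain when rows are permuted.
derive_seed <- function(master, iter, i) {
  if (is.character(i)) i <- string_key(i)
  s <- (as.numeric(master) %% 2147483647) * 48271 %% 2147483647
  s <- (s + iter * 2654435.0 + i * 97.0) %% 2147483647
  as.integer(s) + 1L
}

string_key <- function(x) {
  codes <- utf8ToInt(x)
  k <- 0
  for (c in codes) k <- (k * 131 + c) %% 30269
  k
}

#' E-step: sample latent log-ratios for every community
#'
#' Runs [mh_sample()] independently for each sample `i` with prior mean
#' \eqn{\mu_i = X_i^T \gamma} and a shared precision matrix. Chains are
#' seeded per sample from the master seed, so the result is identical for a
#' fixed seed regardless of the order in which samples are processed.
#'
#' @param W_rho Strictly positive (perturbed) sample-by-taxon matrix.
#' @param X `n x p` design matrix.
#' @param gamma `p x (Q-1)` coefficient matrix.
#' @param sigma_inv `(Q-1) x (Q-1)` precision matrix.
#' @param base Base taxon index.
#' @param cfg An [mh_config()].
#' @param seed Master integer seed.
#' @param iter EM iteration number (enters the per-sample seed derivation).
#' @return A list with `draws` (list of `r_draws x (Q-1)` matrices, one per
#'   sample) and `acceptance_rates` (numeric vector of length `n`).
#' @export
e_step <- function(W_rho, X, gamma, sigma_inv, base, cfg = mh_config(),
                   seed = 1L, iter = 1L) {
  n <- nrow(W_rho)
  if (nrow(X) != n) stop("`W_rho` and `X` must have the same number of rows",
                         call. = FALSE)
  mu <- X %*% gamma
  keys <- rownames(W_rho) %||% seq_len(n)
  out <- purrr::map(seq_len(n), function(i) {
    mh_sample(W_rho[i, ], mu[i, ], sigma_inv, base, cfg,
              seed = derive_seed(seed, iter, keys[i]))
  })
  list(draws = purrr::map(out, "draws"),
       acceptance_rates = purrr::map_dbl(out, "acceptance_rate"))
}

#' M-step: closed-form parameter update
#'
#' Given `R` retained draws per sample, updates
#' \deqn{\gamma^{(t+1)} = \frac1R \sum_r (X^TX)^\dagger X^T Y^{(r)}, \qquad
#'  \Sigma^{(t+1)} = \frac1{nR} \sum_r \sum_i (Y_i^{(r)} - \mu_i)
#'  (Y_i^{(r)} - \mu_i)^T,}
#' where by default \eqn{\mu} is the previous iteration's mean `mu_t` (as
#' printed in the source update); with `center_at_updated_mean = TRUE` the
#' freshly updated mean \eqn{X\gamma^{(t+1)}} is used instead. Rank-deficient
#' `X` is handled through the generalized inverse.
#'
#' @param draws List of `R x (Q-1)` draw matrices, one per sample.
#' @param X `n x p` design matrix.
#' @param mu_t `n x (Q-1)` matrix of previous-iteration means.
#' @param center_at_updated_mean See Description.
#' @return A list with `gamma` (`p x (Q-1)`), `sigma` (`(Q-1) x (Q-1)`,
#'   symmetric PSD) and `mu` (`n x (Q-1)`, the updated mean).
#' @export
m_step <- function(draws, X, mu_t, center_at_updated_mean = FALSE) {
  n <- length(draws)
  R <- nrow(draws[[1]])
  K <- ncol(draws[[1]])
  Ybar <- do.call(rbind, purrr::map(draws, colMeans)) # n x K
  gamma <- pinv(crossprod(X)) %*% crossprod(X, Ybar)  # p x K
  mu_new <- X %*% gamma
  center <- if (center_at_updated_mean) mu_new else mu_t
  sigma <- matrix(0, K, K)
  for (i in seq_len(n)) {
    resid <- sweep(draws[[i]], 2, center[i, ])
    sigma <- sigma + crossprod(resid)
  }
  sigma <- symmetrize(sigma / (n * R))
  list(gamma = gamma, sigma = sigma, mu = mu_new)
}

#' Precision (inverse covariance) estimate from a covariance matrix
#'
#' Forms the precision matrix used inside the E-step. `"naive"` is the
#' Moore-Penrose generalized inverse; `"diagonal"` inverts only the diagonal
#' (zero diagonal entries contribute zero), allowing overdispersion but no
#' between-taxon interactions; `"glasso"` fits an L1-penalized Gaussian
#' likelihood over a log-spaced penalty path and selects the penalty by
#' subsample-based edge-stability (instability threshold 0.05).
#'
#' @param sigma Symmetric covariance matrix.
#' @param method One of `"naive"`, `"diagonal"`, `"glasso"`.
#' @param data Optional observation matrix (rows = observations) used for the
#'   stability subsampling; if absent, Gaussian pseudo-observations are drawn
#'   from `N(0, sigma)`.
#' @param seed Seed for the stability subsampling.
#' @return A symmetric precision matrix of the same dimension as `sigma`.
#' @export
estimate_precision <- function(sigma, method = c("naive", "diagonal", "glasso"),
                               data = NULL, seed = 1L) {
  method <- match.arg(method)
  if (!isTRUE(all.equal(sigma, t(sigma), tolerance = 1e-8))) {
    stop("`sigma` must be symmetric", call. = FALSE)
  }
  sigma <- symmetrize(sigma)
  switch(method,
    naive = pinv(sigma),
    diagonal = {
      d <- diag(sigma)
      diag(ifelse(d > 0, 1 / d, 0), nrow = nrow(sigma))
    },
    glasso = glasso_stability(sigma, data = data, seed = seed)
  )
}

#' Fit the logistic-normal multinomial model by Monte-Carlo EM
#'
#' Estimates the regression coefficients `gamma` (`p x (Q-1)`) and latent
#' covariance `sigma` (`(Q-1) x (Q-1)`) of the log-ratio model: latent
#' log-ratios `Y_i ~ N(X_i' gamma, sigma)`, counts
#' `W_i ~ Multinomial(M_i, alr_inverse(Y_i))`. The E-step draws latent
#' log-ratios by Metropolis sampling; the M-step is closed form.
#' Initialization is deterministic: `gamma` by least squares of the observed
#' (perturbed) log-ratios on `X`, `sigma` as the residual covariance.
#'
#' @param counts Sample-by-taxon count matrix or data frame (raw counts;
#'   perturbation is applied internally).
#' @param X Design matrix (`n x p`). Defaults to intercept-only.
#' @param base Base taxon index; defaults to [choose_base_taxon()].
#' @param rho Zero-perturbation added to the counts (see [perturb()]).
#' @param mh An [mh_config()].
#' @param em An [em_config()].
#' @param seed Integer master seed; the fit is bit-identical across runs for
#'   a fixed seed.
#' @return An object of class `logratio_fit`: a list with elements `gamma`,
#'   `sigma`, `base`, `rho`, `X`, `taxa`, `samples`, `trace` (per-iteration
#'   tibble of parameter norms and mean MH acceptance), `mh`, `em`, `seed`.
#' @examples
#' design <- design_from_template(n = 12, Q = 8, seed = 2)
#' sim <- simulate_dataset(design, seed = 3)
#' fit <- fit_logratio(sim$W, design$X, mh = mh_config(burn = 50, r_draws = 50),
#'                     em = em_config(n_iter = 2), seed = 4)
#' fit$gamma[1, 1:3]
#' @export
fit_logratio <- function(counts, X = NULL, base = NULL, rho = 0.5,
                         mh = mh_config(), em = em_config(), seed = 1L) {
  W <- as_count_matrix(counts)
  n <- nrow(W)
  Q <- ncol(W)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(rownames(W), "(Intercept)"))
  X <- as.matrix(X)
  if (nrow(X) != n) stop("`counts` and `X` must have the same number of rows",
                         call. = FALSE)
  if (is.null(rownames(X))) rownames(X) <- rownames(W)
  p <- ncol(X)
  if (n == 1L && p > 1L) {
    stop("cannot fit p > 1 covariates to a single sample", call. = FALSE)
  }
  if (p > n) warning("more covariates than samples (p > n); ",
                     "estimates will be poorly determined", call. = FALSE)
  if (any(apply(X, 2, function(col) all(col == 0)))) {
    warning("`X` contains an all-zero column", call. = FALSE)
  }
  if (is.null(base)) base <- choose_base_taxon(W)
  base <- check_base(base, Q)

  W_rho <- perturb(W, rho)
  Y_obs <- alr_rows(W_rho / rowSums(W_rho), base) # n x (Q-1)
  if (n == 1L) Y_obs <- matrix(Y_obs, nrow = 1L)

  # deterministic initialization: OLS + residual covariance (MLE scaling)
  gamma <- pinv(crossprod(X)) %*% crossprod(X, Y_obs)
  mu <- X %*% gamma
  resid <- Y_obs - mu
  sigma <- symmetrize(crossprod(resid) / n)

  trace <- vector("list", em$n_iter)
  for (t in seq_len(em$n_iter)) {
    omega <- estimate_precision(sigma, em$precision_method,
                                data = resid, seed = derive_seed(seed, t, 0L))
    es <- e_step(W_rho, X, gamma, omega, base, mh, seed = seed, iter = t)
    ms <- m_step(es$draws, X, mu,
                 center_at_updated_mean = em$center_at_updated_mean)
    gamma <- ms$gamma
    sigma <- ms$sigma
    mu <- ms$mu
    resid <- Y_obs - mu
    trace[[t]] <- tibble::tibble(
      iteration = t,
      gamma_norm = sqrt(sum(gamma^2)),
      sigma_norm = sqrt(sum(sigma^2)),
      mean_acceptance = mean(es$acceptance_rates)
    )
  }

  structure(list(
    gamma = gamma, sigma = sigma, base = as.integer(base), rho = rho,
    X = X, taxa = colnames(W), samples = rownames(W),
    trace = dplyr::bind_rows(trace), mh = mh, em = em, seed = seed,
    n = n, Q = Q, p = p, M = rowSums(W)
  ), class = "logratio_fit")
}

#' @export
print.logratio_fit <- function(x, ...) {
  cat(sprintf("Logistic-normal multinomial fit: %d samples, %d taxa, %d covariates\n",
              x$n, x$Q, x$p))
  cat(sprintf("Base taxon: %d%s; perturbation rho = %g\n", x$base,
              if (!is.null(x$taxa)) paste0(" (", x$taxa[x$base], ")") else "",
              x$rho))
  cat(sprintf("EM iterations: %d; precision: %s; mean MH acceptance (final): %.1f%%\n",
              x$em$n_iter, x$em$precision_method,
              100 * utils::tail(x$trace$mean_acceptance, 1)))
  invisible(x)
}
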
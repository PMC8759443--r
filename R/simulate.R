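#' Construct a simulation design for the log-ratio model
#'
#' Bundles and validates the ingredients needed to simulate from the
#' logistic-normal multinomial model: design matrix `X` (`n x p`),
#' coefficients `gamma` (`p x (Q-1)`), latent covariance `sigma`
#' (`(Q-1) x (Q-1)` PSD), and per-sample sequencing depths `M`.
#' The latent log-ratios are taken relative to the last taxon (`base = Q`).
#'
#' @param X Design matrix.
#' @param gamma Coefficient matrix.
#' @param sigma Latent covariance matrix.
#' @param M Integer vector of per-sample total counts (all `>= 1`).
#' @return An object of class `simulation_design`.
#' @seealso [design_from_template()], [simulate_dataset()]
#' @export
simulation_design <- function(X, gamma, sigma, M) {
  X <- as.matrix(X); gamma <- as.matrix(gamma); sigma <- as.matrix(sigma)
  n <- nrow(X); p <- ncol(X); K <- ncol(gamma); Q <- K + 1L
  if (nrow(gamma) != p) stop("`gamma` must have `ncol(X)` rows", call. = FALSE)
  if (nrow(sigma) != K || ncol(sigma) != K) {
    stop("`sigma` must be (Q-1) x (Q-1) to match `gamma`", call. = FALSE)
  }
  if (!isTRUE(all.equal(sigma, t(sigma), tolerance = 1e-8))) {
    stop("`sigma` must be symmetric", call. = FALSE)
  }
  ev <- eigen(symmetrize(sigma), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("`sigma` must be positive semi-definite", call. = FALSE)
  }
  if (length(M) != n || any(M < 1) || any(M != round(M))) {
    stop("`M` must be `n` integer totals, all >= 1", call. = FALSE)
  }
  structure(list(n = n, Q = Q, p = p, X = X, gamma = gamma,
                 sigma = symmetrize(sigma), M = as.integer(round(M)),
                 base = Q),
            class = "simulation_design")
}

#' Two-group simulation design at microbiome scale
#'
#' Builds the benchmark design used throughout the package's simulation
#' checks: an intercept plus a binary group indicator, with the first
#' `(1 - group_fraction)` of samples in the reference group
#' (`X = [1, (0 ... 0, 1 ... 1)']`). Defaults mirror a small 16S survey:
#' `n = 12` communities, a third of them in the second group, sequencing
#' depths drawn uniformly between `1e4` and `1e5`.
#'
#' When `gamma`/`sigma` are not supplied they are generated randomly:
#' intercept log-ratios `N(0, 2^2)` (a realistically skewed community),
#' group effects `N(0, 0.5^2)`, and
#' `sigma = network_strength * A A' / k + sigma_diag * I` with
#' `A` a `(Q-1) x k` standard normal matrix, `k = max(2, (Q-1) %/% 10)`.
#' `network_strength` scales the between-taxon (off-diagonal) structure:
#' 0 gives a diagonal covariance (no network), values around 1 a moderate
#' network, larger values a strongly networked community.
#'
#' @param n Number of samples.
#' @param Q Number of taxa.
#' @param group_fraction Fraction of samples in the second group; 0 gives an
#'   intercept-only design.
#' @param gamma,sigma Optional parameter matrices (see
#'   [simulation_design()]).
#' @param M Optional per-sample depths.
#' @param network_strength,sigma_diag Knobs for the random `sigma` (ignored
#'   when `sigma` is supplied).
#' @param depth_range Range from which depths are drawn when `M` is absent.
#' @param seed Seed for the random parameter generation.
#' @return A [simulation_design()].
#' @examples
#' d <- design_from_template(n = 12, Q = 20, seed = 1)
#' table(d$X[, 2])
#' @export
design_from_template <- function(n = 12L, Q = 200L, group_fraction = 1 / 3,
                                 gamma = NULL, sigma = NULL, M = NULL,
                                 network_strength = 1, sigma_diag = 0.5,
                                 depth_range = c(1e4, 1e5), seed = 1L) {
  if (group_fraction < 0 || group_fraction > 1) {
    stop("`group_fraction` must be in [0, 1]", call. = FALSE)
  }
  n_grp <- round(n * group_fraction)
  X <- if (n_grp == 0) {
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    cbind("(Intercept)" = rep(1, n),
          group = c(rep(0, n - n_grp), rep(1, n_grp)))
  }
  K <- Q - 1L
  set.seed(seed)
  if (is.null(gamma)) {
    gamma <- rbind(stats::rnorm(K, 0, 2),
                   if (ncol(X) == 2) stats::rnorm(K, 0, 0.5))
    if (ncol(X) == 1) gamma <- matrix(gamma[1, ], 1, K)
  }
  if (is.null(sigma)) {
    k <- max(2L, K %/% 10L)
    A <- matrix(stats::rnorm(K * k), K, k)
    sigma <- network_strength * tcrossprod(A) / k + sigma_diag * diag(K)
  }
  if (is.null(M)) {
    M <- round(stats::runif(n, depth_range[1], depth_range[2]))
  }
  simulation_design(X, gamma, sigma, M)
}

#' Derive simulation parameters from an existing count table
#'
#' Mirrors the benchmark construction used for variance-calibration studies:
#' given a count table and design matrix, compute the observed (perturbed)
#' log-ratios `Y = alr((W + rho) / rowsums)` relative to the chosen base
#' taxon, set `gamma = (X'X)^-1 X'Y`, `sigma` to the covariance of the
#' residuals `Y - X gamma`, and keep the observed sequencing depths. Data
#' simulated from the resulting design is self-consistent with how the model
#' is fitted (the latent scale is the perturbed log-ratio scale), which is
#' what makes bootstrap calibration studies meaningful.
#'
#' Taxa are reordered so the base taxon sits in the last column (the
#' simulator's convention); the returned design carries the ordering as the
#' `"taxon_order"` attribute.
#'
#' @param counts Sample-by-taxon count matrix ("mother" dataset).
#' @param X Design matrix (`n x p`).
#' @param rho Zero perturbation used to form the log-ratios.
#' @param base Base taxon index in `counts`; defaults to
#'   [choose_base_taxon()].
#' @return A [simulation_design()] with the derived `gamma`, `sigma` and the
#'   observed depths.
#' @export
design_from_counts <- function(counts, X, rho = 0.5, base = NULL) {
  W <- as_count_matrix(counts)
  X <- as.matrix(X)
  if (is.null(base)) base <- choose_base_taxon(W)
  base <- check_base(base, ncol(W))
  ord <- c(setdiff(seq_len(ncol(W)), base), base)
  W <- W[, ord, drop = FALSE]
  W_rho <- perturb(W, rho)
  Q <- ncol(W)
  Y <- alr_rows(W_rho / rowSums(W_rho), Q)
  gamma <- pinv(crossprod(X)) %*% crossprod(X, Y)
  resid <- Y - X %*% gamma
  sigma <- symmetrize(stats::cov(resid))
  des <- simulation_design(X, gamma, sigma, rowSums(W))
  attr(des, "taxon_order") <- ord
  des
}

#' Simulate a dataset from the log-ratio model
#'
#' Draws, for each sample `i`, latent log-ratios
#' `Y_i ~ N(X_i' gamma, sigma)`, forms the latent composition
#' `Z_i = alr_inverse(Y_i)`, and draws counts
#' `W_i ~ Multinomial(M_i, Z_i)`. All three matrices are returned so tests
#' can use the latent truth as an oracle. Deterministic given `seed`.
#'
#' @param design A [simulation_design()].
#' @param seed Integer seed.
#' @return A list with `W` (`n x Q` integer counts), `Z` (`n x Q` latent
#'   compositions), `Y` (`n x (Q-1)` latent log-ratios) and the `design`.
#' @export
simulate_dataset <- function(design, seed = 1L) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(seed)
  mu <- design$X %*% design$gamma
  Y <- mu + rmvnorm_psd(design$n, numeric(design$Q - 1L), design$sigma)
  Z <- alr_inverse_rows(Y, design$base)
  W <- matrix(0L, design$n, design$Q)
  for (i in seq_len(design$n)) {
    W[i, ] <- as.integer(stats::rmultinom(1, design$M[i], Z[i, ]))
  }
  dimnames(W) <- list(paste0("sample_", seq_len(design$n)),
                      paste0("taxon_", seq_len(design$Q)))
  dimnames(Z) <- dimnames(W)
  list(W = W, Z = Z, Y = Y, design = design)
}
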
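#' Bootstrap variance of model-based diversity estimates
#'
#' Estimates the sampling variance of the model-based alpha- and
#' beta-diversity estimates by refitting the whole pipeline on bootstrap
#' datasets.
#'
#' * `scheme = "parametric"` (default): `B` datasets are simulated from the
#'   fitted log-ratio model (`mu = X gamma_hat`, `sigma = sigma_hat`, with
#'   the observed sequencing depths), each is refitted with the original
#'   MH/EM configuration, and the sample variance of the resulting estimates
#'   is reported. Calibration studies show this scheme is approximately
#'   unbiased for the true estimator variance.
#' * `scheme = "nonparametric"`: `B` resamples of `n_sub` sample indices are
#'   drawn with replacement, the model refitted on each resample, and the
#'   variance of the estimates taken; this scheme tends to *underestimate*
#'   the true variance and is provided for comparison. A resample whose
#'   design matrix is rank deficient is redrawn (up to 10 attempts, then
#'   kept with a warning).
#'
#' @param fit A [fit_logratio()] object.
#' @param counts The count table the model was fitted to.
#' @param scheme `"parametric"` or `"nonparametric"`.
#' @param b_reps Number of bootstrap datasets `B` (>= 2). Default 5.
#' @param n_sub Resample size for the nonparametric scheme; default `n`.
#' @param indices Alpha indices for which variances are computed.
#' @param beta_indices Beta indices for which variances are computed.
#' @param seed Integer seed; results are reproducible given the seed.
#' @param keep_replicates Keep the per-replicate estimates (for diagnostics)?
#' @return A list with `alpha` (tibble: `sample`, `index`, `variance`,
#'   `std_error`), `beta` (named list of symmetric variance matrices), and,
#'   if requested, `replicates` (long tibble of per-replicate estimates).
#' @export
bootstrap_variance <- function(fit, counts,
                               scheme = c("parametric", "nonparametric"),
                               b_reps = 5L, n_sub = NULL,
                               indices = c("shannon", "simpson"),
                               beta_indices = c("bray_curtis", "euclidean"),
                               seed = 1L, keep_replicates = FALSE) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(fit, "logratio_fit"))
  if (b_reps < 2) stop("`b_reps` must be at least 2 for a variance",
                       call. = FALSE)
  W <- as_count_matrix(counts)
  n <- nrow(W)
  if (is.null(n_sub)) n_sub <- n
  if (n_sub < 1 || n_sub > n) stop("`n_sub` must be in 1..n", call. = FALSE)

  refit_estimates <- function(W_b, X_b, b) {
    fit_b <- fit_logratio(W_b, X_b, base = fit$base, rho = fit$rho,
                          mh = fit$mh, em = fit$em,
                          seed = derive_seed(seed, 1000L + b, 0L))
    # evaluate at the ORIGINAL covariate rows so replicates are comparable
    fc_b <- fitted_compositions(fit_b, newdata = fit$X)
    list(alpha = alpha_estimates(fc_b, index = indices),
         beta = purrr::map(rlang::set_names(beta_indices),
                           ~ beta_estimates(fc_b, .x)))
  }

  reps <- vector("list", b_reps)
  if (scheme == "parametric") {
    des <- simulation_design(fit$X, fit$gamma, fit$sigma, fit$M)
    # simulate relative to the fitted base taxon: reorder so that the fitted
    # base occupies the last position used by the simulator, then undo
    ord <- c(setdiff(seq_len(fit$Q), fit$base), fit$base)
    inv_ord <- order(ord)
    for (b in seq_len(b_reps)) {
      sim <- simulate_dataset(des, seed = derive_seed(seed, 2000L + b, 0L))
      W_b <- sim$W[, inv_ord, drop = FALSE]
      colnames(W_b) <- colnames(W)
      rownames(W_b) <- rownames(W)
      reps[[b]] <- refit_estimates(W_b, fit$X, b)
    }
  } else {
    set.seed(derive_seed(seed, 3000L, 0L))
    for (b in seq_len(b_reps)) {
      idx <- sample.int(n, n_sub, replace = TRUE)
      attempt <- 1L
      while (qr(fit$X[idx, , drop = FALSE])$rank < ncol(fit$X) &&
             attempt < 10L) {
        idx <- sample.int(n, n_sub, replace = TRUE)
        attempt <- attempt + 1L
      }
      if (qr(fit$X[idx, , drop = FALSE])$rank < ncol(fit$X)) {
        warning("bootstrap resample design is rank deficient after 10 draws; ",
                "keeping it", call. = FALSE)
      }
      W_b <- W[idx, , drop = FALSE]
      rownames(W_b) <- paste0(rownames(W)[idx], "_", seq_along(idx))
      reps[[b]] <- refit_estimates(W_b, fit$X[idx, , drop = FALSE], b)
    }
  }

  alpha_long <- purrr::imap_dfr(reps, function(r, b) {
    dplyr::mutate(r$alpha, replicate = b)
  })
  alpha_var <- alpha_long |>
    dplyr::group_by(.data$sample, .data$index) |>
    dplyr::summarise(variance = stats::var(.data$estimate), .groups = "drop") |>
    dplyr::mutate(std_error = sqrt(.data$variance))

  beta_var <- purrr::map(rlang::set_names(beta_indices), function(ix) {
    stack <- purrr::map(reps, ~ .x$beta[[ix]])
    v <- apply(simplify2array(stack), c(1, 2), stats::var)
    symmetrize(v)
  })

  out <- list(alpha = alpha_var, beta = beta_var, scheme = scheme,
              b_reps = b_reps, n_sub = if (scheme == "nonparametric") n_sub else NA)
  if (keep_replicates) out$replicates <- alpha_long
  out
}
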
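#' Fitted latent compositions for covariate profiles
#'
#' Computes \eqn{\hat{Z}_i = \phi^{-1}(X_i^T \hat\gamma)} for each requested
#' covariate row. Rows with identical covariates yield identical
#' compositions, so estimates are organised per covariate *profile* (unique
#' row of `X`) and mapped back to samples. Profiles need not appear in the
#' training data: diversity can be predicted for unsurveyed communities with
#' known covariates.
#'
#' @param fit A [fit_logratio()] object.
#' @param newdata Optional matrix of covariate rows (`ncol == p`); defaults
#'   to the design matrix used to fit.
#' @return An object of class `fitted_compositions`: a list with `z`
#'   (rows = requested covariate rows, valid compositions), `profile`
#'   (integer profile id per row), `profiles` (unique covariate rows),
#'   `z_profile` (one composition per profile), `base`, `taxa`, `labels`.
#' @export
fitted_compositions <- function(fit, newdata = NULL) {
  stopifnot(inherits(fit, "logratio_fit"))
  X_rows <- if (is.null(newdata)) fit$X else as.matrix(newdata)
  if (ncol(X_rows) != nrow(fit$gamma)) {
    stop(sprintf("`newdata` must have %d columns to match the fitted model",
                 nrow(fit$gamma)), call. = FALSE)
  }
  labels <- rownames(X_rows)
  if (is.null(labels)) labels <- paste0("row_", seq_len(nrow(X_rows)))
  key <- apply(X_rows, 1, paste, collapse = "\r")
  profiles_idx <- !duplicated(key)
  profile <- match(key, key[profiles_idx])
  Y_hat <- X_rows[profiles_idx, , drop = FALSE] %*% fit$gamma
  z_profile <- alr_inverse_rows(Y_hat, fit$base)
  if (nrow(Y_hat) == 1L) z_profile <- matrix(z_profile, nrow = 1L)
  colnames(z_profile) <- fit$taxa
  z <- z_profile[profile, , drop = FALSE]
  rownames(z) <- labels
  structure(list(z = z, profile = profile,
                 profiles = X_rows[profiles_idx, , drop = FALSE],
                 z_profile = z_profile, base = fit$base, taxa = fit$taxa,
                 labels = labels),
            class = "fitted_compositions")
}

alpha_index_fun <- function(index) {
  switch(index,
         shannon = shannon,
         simpson = simpson,
         stop(sprintf("unknown alpha-diversity index '%s'", index),
              call. = FALSE))
}

beta_index_fun <- function(index) {
  switch(index,
         bray_curtis = bray_curtis,
         euclidean = euclidean,
         stop(sprintf("unknown beta-diversity index '%s'", index),
              call. = FALSE))
}

#' Model-based alpha-diversity estimates
#'
#' Applies an alpha-diversity index to each fitted composition: the
#' model-based estimate \eqn{\hat\alpha_i = f(\hat{Z}_i)}.
#'
#' @param fc A [fitted_compositions()] object.
#' @param index `"shannon"` or `"simpson"` (may be a vector of both).
#' @return A tibble with columns `sample`, `profile`, `index`, `estimate`.
#' @export
alpha_estimates <- function(fc, index = c("shannon", "simpson")) {
  stopifnot(inherits(fc, "fitted_compositions"))
  index <- match.arg(index, several.ok = TRUE)
  purrr::map_dfr(index, function(ix) {
    f <- alpha_index_fun(ix)
    per_profile <- apply(fc$z_profile, 1, f)
    tibble::tibble(sample = fc$labels,
                   profile = fc$profile,
                   index = ix,
                   estimate = per_profile[fc$profile])
  })
}

#' Model-based beta-diversity estimates
#'
#' Applies a beta-diversity index to every pair of fitted compositions:
#' \eqn{\hat\beta_{ij} = g(\hat{Z}_i, \hat{Z}_j)}. Note that two samples
#' sharing a covariate profile have identical fitted compositions, so their
#' model-based beta-diversity is zero by construction; within-profile
#' dissimilarity is not an estimand of this model.
#'
#' @param fc A [fitted_compositions()] object.
#' @param index `"bray_curtis"` or `"euclidean"`.
#' @return A symmetric matrix with zero diagonal over the requested rows
#'   (sample-level, labelled by `fc$labels`).
#' @export
beta_estimates <- function(fc, index = c("bray_curtis", "euclidean")) {
  stopifnot(inherits(fc, "fitted_compositions"))
  index <- match.arg(index)
  g <- beta_index_fun(index)
  n_prof <- nrow(fc$z_profile)
  Bp <- matrix(0, n_prof, n_prof)
  if (n_prof > 1) {
    for (i in seq_len(n_prof - 1)) {
      for (j in seq(i + 1, n_prof)) {
        Bp[i, j] <- Bp[j, i] <- g(fc$z_profile[i, ], fc$z_profile[j, ])
      }
    }
  }
  B <- Bp[fc$profile, fc$profile, drop = FALSE]
  dimnames(B) <- list(fc$labels, fc$labels)
  B
}

#' Sensitivity of diversity estimates to base taxon or perturbation
#'
#' Refits the full model for each candidate base taxon (or each candidate
#' zero-perturbation `rho`) and tabulates the resulting alpha-diversity
#' estimates, reproducing the style of sensitivity analysis in which the
#' log-ratio denominator or the zero offset is varied. Each candidate is a
#' complete refit, not a shortcut.
#'
#' @param counts Sample-by-taxon count matrix or data frame.
#' @param X Optional design matrix (intercept-only when absent).
#' @param scan `"base_taxon"` or `"rho"`.
#' @param candidates Vector of candidate base-taxon indices or `rho` values.
#' @param indices Alpha indices to tabulate.
#' @param rho,base Fixed value of the non-scanned quantity.
#' @param mh,em,seed Passed to [fit_logratio()].
#' @return A tibble with columns `candidate`, `sample`, `profile`, `index`,
#'   `estimate`.
#' @export
sensitivity_scan <- function(counts, X = NULL,
                             scan = c("base_taxon", "rho"),
                             candidates,
                             indices = c("shannon", "simpson"),
                             rho = 0.5, base = NULL,
                             mh = mh_config(), em = em_config(), seed = 1L) {
  scan <- match.arg(scan)
  if (length(candidates) < 1) stop("`candidates` must be nonempty", call. = FALSE)
  W <- as_count_matrix(counts)
  if (scan == "base_taxon" &&
      any(candidates < 1 | candidates > ncol(W))) {
    stop("candidate base taxon outside the count table", call. = FALSE)
  }
  purrr::map_dfr(candidates, function(cand) {
    fit <- if (scan == "base_taxon") {
      fit_logratio(W, X, base = cand, rho = rho, mh = mh, em = em, seed = seed)
    } else {
      fit_logratio(W, X, base = base, rho = cand, mh = mh, em = em, seed = seed)
    }
    alpha_estimates(fitted_compositions(fit), index = indices) |>
      dplyr::mutate(candidate = cand, .before = 1)
  })
}
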
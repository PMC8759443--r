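#' Estimate diversity under a co-occurrence-aware model
#'
#' The main entry point. Fits the logistic-normal multinomial (log-ratio)
#' model to a sample-by-taxon count table, turns the fitted parameters into
#' alpha- and beta-diversity estimates per covariate profile, and (optionally)
#' attaches bootstrap standard errors. Pipeline: perturb zeros, choose the
#' base taxon, fit by Monte-Carlo EM, form fitted compositions, evaluate the
#' requested indices, bootstrap.
#'
#' Unlike plug-in estimators, which describe the sample, these estimates
#' target the diversity of the community from which the sample was drawn,
#' pooling information across samples through the covariates.
#'
#' @param counts Sample-by-taxon count matrix or data frame (samples as
#'   rows). A character column, if present, is used as sample identifiers.
#' @param X Optional design matrix (`n x p`); intercept-only when absent.
#' @param indices Diversity indices to estimate; any of `"shannon"`,
#'   `"simpson"` (alpha), `"bray_curtis"`, `"euclidean"` (beta).
#' @param base_taxon Base taxon index, or `NULL` to select the most abundant
#'   taxon present in every sample.
#' @param rho Zero-perturbation added to all counts (default 0.5).
#' @param variance `"parametric"` (default), `"nonparametric"`, or `"none"`.
#' @param b_reps Bootstrap replicates (default 5).
#' @param n_sub Nonparametric resample size (default `n`).
#' @param mh,em Sampler and EM configurations ([mh_config()], [em_config()]).
#' @param seed Master seed; the whole pipeline is reproducible given it.
#' @return An object of class `netdiv_fit` with elements `fit`
#'   (the [fit_logratio()] object), `compositions`
#'   ([fitted_compositions()]), `alpha` (tibble with `sample`, `profile`,
#'   `index`, `estimate` and, when bootstrapped, `variance`, `std_error`),
#'   `beta` (named list of symmetric dissimilarity matrices),
#'   `beta_variance`, and the call configuration. Use [tidy()], [glance()]
#'   and [autoplot()] to inspect it.
#' @examples
#' design <- design_from_template(n = 6, Q = 8, seed = 1,
#'                                depth_range = c(500, 1000))
#' sim <- simulate_dataset(design, seed = 2)
#' est <- netdiv(sim$W, design$X, variance = "none",
#'               mh = mh_config(burn = 50, r_draws = 50),
#'               em = em_config(n_iter = 2), seed = 3)
#' tidy(est)
#' @export
netdiv <- function(counts, X = NULL,
                   indices = c("shannon", "simpson", "bray_curtis", "euclidean"),
                   base_taxon = NULL, rho = 0.5,
                   variance = c("parametric", "nonparametric", "none"),
                   b_reps = 5L, n_sub = NULL,
                   mh = mh_config(), em = em_config(), seed = 1L) {
  variance <- match.arg(variance)
  indices <- match.arg(indices, several.ok = TRUE)
  alpha_idx <- intersect(indices, c("shannon", "simpson"))
  beta_idx <- intersect(indices, c("bray_curtis", "euclidean"))
  W <- as_count_matrix(counts)
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (is.null(rownames(X))) rownames(X) <- rownames(W)
  }

  fit <- fit_logratio(W, X, base = base_taxon, rho = rho,
                      mh = mh, em = em, seed = seed)
  fc <- fitted_compositions(fit)
  alpha <- if (length(alpha_idx)) alpha_estimates(fc, alpha_idx) else NULL
  beta <- purrr::map(rlang::set_names(beta_idx), ~ beta_estimates(fc, .x))

  beta_var <- NULL
  if (variance != "none") {
    bv <- bootstrap_variance(fit, W, scheme = variance, b_reps = b_reps,
                             n_sub = n_sub,
                             indices = if (length(alpha_idx)) alpha_idx else "shannon",
                             beta_indices = beta_idx,
                             seed = derive_seed(seed, 5000L, 0L))
    if (!is.null(alpha)) {
      alpha <- dplyr::left_join(alpha, bv$alpha, by = c("sample", "index"))
    }
    beta_var <- bv$beta
  }

  structure(list(fit = fit, compositions = fc, alpha = alpha, beta = beta,
                 beta_variance = beta_var, indices = indices,
                 variance = variance, b_reps = b_reps, seed = seed),
            class = "netdiv_fit")
}

#' @export
print.netdiv_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$alpha)) {
    cat("\nAlpha-diversity estimates (first rows):\n")
    print(utils::head(x$alpha, 6))
  }
  if (length(x$beta)) {
    cat(sprintf("\nBeta-diversity matrices: %s (%d x %d)\n",
                paste(names(x$beta), collapse = ", "),
                nrow(x$beta[[1]]), ncol(x$beta[[1]])))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy diversity estimates from a netdiv fit
#'
#' Returns the per-sample alpha-diversity estimates (and, with
#' `matrices = TRUE`, the pairwise beta-diversity values in long form).
#'
#' @param x A `netdiv_fit`.
#' @param matrices Include beta-diversity pairs? Default `FALSE`.
#' @param ... Unused.
#' @return A tibble with columns `sample`, `profile`, `index`, `estimate`
#'   and (when bootstrapped) `variance`, `std_error`; beta rows carry
#'   `sample` and `other` identifiers.
#' @export
tidy.netdiv_fit <- function(x, matrices = FALSE, ...) {
  out <- x$alpha %||% tibble::tibble()
  if (matrices && length(x$beta)) {
    beta_long <- purrr::imap_dfr(x$beta, function(B, ix) {
      pairs <- which(upper.tri(B), arr.ind = TRUE)
      tibble::tibble(sample = rownames(B)[pairs[, 1]],
                     other = colnames(B)[pairs[, 2]],
                     index = ix,
                     estimate = B[pairs])
    })
    out <- dplyr::bind_rows(out, beta_long)
  }
  out
}

#' One-row summary of a netdiv fit
#'
#' @param x A `netdiv_fit`.
#' @param ... Unused.
#' @return A one-row tibble: sample count, taxa, covariates, base taxon,
#'   perturbation, EM iterations, final mean MH acceptance, bootstrap scheme.
#' @export
glance.netdiv_fit <- function(x, ...) {
  f <- x$fit
  tibble::tibble(
    n = f$n, Q = f$Q, p = f$p, base_taxon = f$base, rho = f$rho,
    em_iterations = f$em$n_iter,
    precision_method = f$em$precision_method,
    mean_acceptance = utils::tail(f$trace$mean_acceptance, 1),
    variance_scheme = x$variance,
    b_reps = if (x$variance == "none") NA_integer_ else x$b_reps
  )
}

#' Tidy coefficients of a log-ratio model fit
#'
#' @param x A `logratio_fit`.
#' @param ... Unused.
#' @return Long tibble of `term` (covariate), `taxon`, `estimate`
#'   (log-ratio regression coefficient relative to the base taxon).
#' @export
tidy.logratio_fit <- function(x, ...) {
  taxa <- x$taxa[-x$base]
  terms <- colnames(x$X) %||% paste0("x", seq_len(x$p))
  tibble::tibble(
    term = rep(terms, times = length(taxa)),
    taxon = rep(taxa, each = length(terms)),
    estimate = as.vector(x$gamma)
  )
}

#' @export
glance.logratio_fit <- function(x, ...) {
  tibble::tibble(n = x$n, Q = x$Q, p = x$p, base_taxon = x$base,
                 rho = x$rho, em_iterations = x$em$n_iter,
                 mean_acceptance = utils::tail(x$trace$mean_acceptance, 1))
}

#' Plot diversity estimates with bootstrap error bars
#'
#' Alpha-diversity estimates per sample, faceted by index, with
#' `+/- 2 * std_error` bars when a bootstrap was run.
#'
#' @param object A `netdiv_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.netdiv_fit <- function(object, ...) {
  d <- object$alpha
  if (is.null(d) || nrow(d) == 0) {
    stop("no alpha-diversity estimates to plot", call. = FALSE)
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$sample, y = .data$estimate)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "estimated diversity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if ("std_error" %in% names(d) && any(is.finite(d$std_error))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$estimate - 2 * .data$std_error,
                   ymax = .data$estimate + 2 * .data$std_error),
      width = 0.2)
  }
  p
}

#' Trace plot of EM convergence diagnostics
#'
#' @param fit A `logratio_fit` or `netdiv_fit`.
#' @return A ggplot of per-iteration parameter norms and MH acceptance.
#' @export
plot_trace <- function(fit) {
  if (inherits(fit, "netdiv_fit")) fit <- fit$fit
  stopifnot(inherits(fit, "logratio_fit"))
  d <- tidyr::pivot_longer(fit$trace, -"iteration",
                           names_to = "diagnostic", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(.data$iteration, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~diagnostic, scales = "free_y") +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
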
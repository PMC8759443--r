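#' Validate a composition (relative abundance vector)
#'
#' A composition is a vector of proportions on the simplex: every entry in
#' `[0, 1]` and the entries summing to one within an absolute tolerance of
#' `1e-10` (double precision).
#'
#' @param z Numeric vector of relative abundances.
#' @param arg Name used in error messages.
#' @return `z`, invisibly, after validation.
#' @keywords internal
check_composition <- function(z, arg = "z") {
  if (!is.numeric(z) || length(z) < 1L) {
    stop(sprintf("`%s` must be a non-empty numeric vector", arg), call. = FALSE)
  }
  if (anyNA(z) || any(z < -1e-12) || any(z > 1 + 1e-12)) {
    stop(sprintf("`%s` is not a valid composition: entries must lie in [0, 1]", arg),
         call. = FALSE)
  }
  if (abs(sum(z) - 1) > 1e-10) {
    stop(sprintf("`%s` is not a valid composition: entries sum to %.12f, not 1",
                 arg, sum(z)), call. = FALSE)
  }
  invisible(z)
}

check_counts <- function(w, arg = "w") {
  if (!is.numeric(w) || length(w) < 1L) {
    stop(sprintf("`%s` must be a non-empty numeric vector", arg), call. = FALSE)
  }
  if (anyNA(w) || any(w < 0) || any(abs(w - round(w)) > 1e-8)) {
    stop(sprintf("`%s` must contain nonnegative integer counts", arg), call. = FALSE)
  }
  if (sum(w) < 1) {
    stop(sprintf("`%s` must contain at least one observation (sum >= 1)", arg),
         call. = FALSE)
  }
  invisible(w)
}

#' Shannon entropy of a composition
#'
#' Computes \eqn{-\sum_q z_q \log z_q} in nats, with the convention
#' \eqn{0 \log 0 = 0}. For a community of `Q` taxa the index lies in
#' `[0, log Q]`, maximised at the uniform composition.
#'
#' @param z A composition: numeric vector of proportions summing to one.
#' @return Shannon entropy (nats), a single number.
#' @examples
#' shannon(rep(1 / 4, 4)) # log(4)
#' shannon(c(0.5, 0.25, 0.25))
#' @seealso [simpson()], [plugin_shannon()]
#' @export
shannon <- function(z) {
  check_composition(z)
  pos <- z > 0
  -sum(z[pos] * log(z[pos]))
}

#' Simpson index of a composition
#'
#' Computes \eqn{\sum_q z_q^2}, the probability that two individuals drawn
#' at random belong to the same taxon. Lies in `[1/Q, 1]`; small values
#' indicate high diversity.
#'
#' @inheritParams shannon
#' @return Simpson index, a single number.
#' @export
simpson <- function(z) {
  check_composition(z)
  sum(z^2)
}

#' Bray-Curtis dissimilarity between two compositions
#'
#' Computes \eqn{1 - \sum_q \min(z_{1q}, z_{2q})}; 0 for identical
#' communities, 1 for communities with disjoint support.
#'
#' @param z1,z2 Compositions of equal length.
#' @return Bray-Curtis dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(z1, z2) {
  check_composition(z1, "z1")
  check_composition(z2, "z2")
  if (length(z1) != length(z2)) {
    stop("`z1` and `z2` must have the same number of taxa", call. = FALSE)
  }
  1 - sum(pmin(z1, z2))
}

#' Euclidean distance between two compositions
#'
#' @inheritParams bray_curtis
#' @return Euclidean distance \eqn{\sqrt{\sum_q (z_{1q} - z_{2q})^2}}.
#' @export
euclidean <- function(z1, z2) {
  check_composition(z1, "z1")
  check_composition(z2, "z2")
  if (length(z1) != length(z2)) {
    stop("`z1` and `z2` must have the same number of taxa", call. = FALSE)
  }
  sqrt(sum((z1 - z2)^2))
}

#' Plug-in (multinomial MLE) Shannon estimator
#'
#' Applies [shannon()] to the observed proportions `w / sum(w)`. This is the
#' maximum likelihood estimate under multinomial sampling and is negatively
#' biased by approximately \eqn{(C - 1) / (2M)} for `C` observed taxa and
#' sequencing depth `M`.
#'
#' @param w Nonnegative integer count vector with at least one observation.
#' @return Estimated Shannon entropy (nats).
#' @export
plugin_shannon <- function(w) {
  check_counts(w)
  shannon(w / sum(w))
}

#' Miller-Maddow bias-corrected Shannon estimator
#'
#' Adds the first-order bias correction \eqn{(C - 1) / (2M)} to the plug-in
#' estimate, where `C` is the number of observed (positive-count) taxa. The
#' true richness is unknown, so the observed richness stands in for it; this
#' is the only computable choice and is an approximation.
#'
#' @inheritParams plugin_shannon
#' @return Bias-corrected Shannon estimate (nats).
#' @export
miller_maddow_shannon <- function(w) {
  check_counts(w)
  c_obs <- sum(w > 0)
  plugin_shannon(w) + (c_obs - 1) / (2 * sum(w))
}

#' Chao-Shen coverage-adjusted Shannon estimator
#'
#' Adjusts for unobserved taxa using the Good-Turing coverage estimate
#' \eqn{\hat{C} = 1 - f_1 / M} (`f_1` = number of singletons). The estimate is
#' \deqn{-\sum_{q: w_q > 0} \frac{\hat{C}\hat{\pi}_q \log(\hat{C}\hat{\pi}_q)}
#'   {1 - (1 - \hat{C}\hat{\pi}_q)^M},}
#' with \eqn{\hat{\pi}_q = w_q / M}. The exponent is taken to be the sample
#' total `M` (the printed source notation is ambiguous between `n` and `M`;
#' the original estimator uses the sample size, which for a single community
#' is its total count).
#'
#' @inheritParams plugin_shannon
#' @return Coverage-adjusted Shannon estimate (nats).
#' @export
chao_shen_shannon <- function(w) {
  check_counts(w)
  m <- sum(w)
  f1 <- sum(w == 1)
  coverage <- 1 - f1 / m
  if (coverage <= 0) {
    stop("Chao-Shen estimator is undefined: estimated coverage is zero ",
         "(every observed taxon is a singleton). Collect more observations ",
         "or use another estimator.", call. = FALSE)
  }
  p <- coverage * w[w > 0] / m
  -sum(p * log(p) / (1 - (1 - p)^m))
}

#' Zero-replace composition
#'
#' Replaces zero counts by 0.5 and renormalises, yielding a strictly positive
#' composition to which any index may be applied. A common device from
#' compositional data analysis for handling sampling zeros.
#'
#' @param w Nonnegative integer count vector with at least one positive entry.
#' @return A strictly positive composition of the same length as `w`.
#' @examples
#' zero_replace_composition(c(2, 0, 2)) # (4/9, 1/9, 4/9)
#' @export
zero_replace_composition <- function(w) {
  check_counts(w)
  w_star <- pmax(w, 0.5)
  w_star / sum(w_star)
}

#' Plug-in Simpson estimator
#'
#' Uncorrected: \eqn{\sum_q (w_q/M)^2}. With `corrected = TRUE` the plug-in
#' value is scaled by \eqn{M/(M-1)}, removing the leading finite-sample bias
#' under multinomial sampling; for the depths typical of amplicon data
#' (`M > 1000`) the two are practically identical.
#'
#' @inheritParams plugin_shannon
#' @param corrected Apply the `M/(M-1)` finite-sample scaling? Default `FALSE`.
#' @return Estimated Simpson index.
#' @export
plugin_simpson <- function(w, corrected = FALSE) {
  check_counts(w)
  m <- sum(w)
  est <- sum((w / m)^2)
  if (corrected) {
    if (m < 2) stop("corrected Simpson estimator requires a total count >= 2",
                    call. = FALSE)
    est <- m / (m - 1) * est
  }
  est
}

#' Plug-in Bray-Curtis estimator from counts
#'
#' Computes \eqn{1 - 2 \sum_q \min(w_{1q}, w_{2q}) / (M_1 + M_2)}. Note that
#' this is the conventional observed Bray-Curtis index, which is not the same
#' as [bray_curtis()] applied to the two proportion vectors unless
#' \eqn{M_1 = M_2}.
#'
#' @param w1,w2 Count vectors over the same taxa.
#' @return Estimated Bray-Curtis dissimilarity in `[0, 1]`.
#' @export
plugin_bray_curtis <- function(w1, w2) {
  check_counts(w1, "w1")
  check_counts(w2, "w2")
  if (length(w1) != length(w2)) {
    stop("`w1` and `w2` must have the same number of taxa", call. = FALSE)
  }
  1 - 2 * sum(pmin(w1, w2)) / (sum(w1) + sum(w2))
}

#' Plug-in Euclidean estimator from counts
#'
#' [euclidean()] applied to the two observed proportion vectors.
#'
#' @inheritParams plugin_bray_curtis
#' @return Estimated Euclidean distance.
#' @export
plugin_euclidean <- function(w1, w2) {
  check_counts(w1, "w1")
  check_counts(w2, "w2")
  if (length(w1) != length(w2)) {
    stop("`w1` and `w2` must have the same number of taxa", call. = FALSE)
  }
  sqrt(sum((w1 / sum(w1) - w2 / sum(w2))^2))
}

#' Classical per-sample diversity estimates for a count table
#'
#' Convenience wrapper applying the count-based comparison estimators to every
#' row of a sample-by-taxon count table. The Chao-Shen column is `NA` for
#' samples whose estimated coverage is zero.
#'
#' @param counts Sample-by-taxon count matrix or data frame (samples as rows).
#' @return A tibble with one row per sample and columns `sample`,
#'   `plugin_shannon`, `miller_maddow_shannon`, `chao_shen_shannon`,
#'   `zero_replace_shannon`, `plugin_simpson`, `corrected_simpson`.
#' @examples
#' W <- rbind(a = c(5, 3, 0, 1), b = c(2, 2, 2, 2))
#' classical_diversity(W)
#' @export
classical_diversity <- function(counts) {
  W <- as_count_matrix(counts)
  purrr::map_dfr(seq_len(nrow(W)), function(i) {
    w <- W[i, ]
    tibble::tibble(
      sample = rownames(W)[i],
      plugin_shannon = plugin_shannon(w),
      miller_maddow_shannon = miller_maddow_shannon(w),
      chao_shen_shannon = tryCatch(chao_shen_shannon(w),
                                   error = function(e) NA_real_),
      zero_replace_shannon = shannon(zero_replace_composition(w)),
      plugin_simpson = plugin_simpson(w),
      corrected_simpson = plugin_simpson(w, corrected = TRUE)
    )
  })
}

# Coerce a counts input (matrix / data.frame, optionally with a sample-id
# first column) to a named numeric matrix, samples as rows.
as_count_matrix <- function(counts) {
  if (is.data.frame(counts)) {
    id_col <- which(vapply(counts, is.character, logical(1)))
    if (length(id_col) > 0) {
      rn <- counts[[id_col[1]]]
      counts <- counts[, -id_col, drop = FALSE]
      counts <- as.matrix(counts)
      rownames(counts) <- rn
    } else {
      counts <- as.matrix(counts)
    }
  }
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("`counts` must be a numeric matrix or data frame of counts",
         call. = FALSE)
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("sample_", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("taxon_", seq_len(ncol(counts)))
  }
  if (anyNA(counts) || any(counts < 0)) {
    bad <- which(is.na(counts) | counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("invalid count at row %s, column %s: counts must be nonnegative",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]),
         call. = FALSE)
  }
  counts
}
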
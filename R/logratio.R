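#' Additive log-ratio transform
#'
#' Maps a strictly positive composition `z` of length `Q` to the vector of
#' log-ratios \eqn{\log(z_q / z_d)} for all taxa `q` other than the base
#' taxon `d`, in ascending taxon order with `d` removed (length `Q - 1`).
#' The transform is a bijection between the open simplex and
#' \eqn{R^{Q-1}}; see [alr_inverse()].
#'
#' Zeros are rejected rather than silently perturbed: perturbation is an
#' explicit, auditable pipeline step ([perturb()]).
#'
#' @param z Strictly positive composition.
#' @param base Integer index of the base (reference) taxon, in `1..Q`.
#' @return Numeric vector of `Q - 1` log-ratios.
#' @examples
#' alr(c(0.5, 0.25, 0.25), base = 3) # c(log(2), 0)
#' @export
alr <- function(z, base) {
  check_composition(z)
  base <- check_base(base, length(z))
  if (any(z <= 0)) {
    stop("`z` contains zero entries; the log-ratio transform requires strictly ",
         "positive abundances. Perturb the counts first (see `perturb()`).",
         call. = FALSE)
  }
  log(z[-base] / z[base])
}

#' Inverse additive log-ratio transform
#'
#' Maps a log-ratio vector `y` of length `Q - 1` back to the simplex:
#' \eqn{z_q = e^{y_q} / (\sum e^{y} + 1)} for non-base taxa and
#' \eqn{z_d = 1 / (\sum e^{y} + 1)} for the base taxon. Computed with a
#' max-shift so large log-ratios do not overflow, and normalised last so the
#' output sums to one exactly.
#'
#' @param y Numeric vector of `Q - 1` finite log-ratios.
#' @param base Integer index the base taxon occupies in the output, in `1..Q`.
#' @return A composition of length `Q`, strictly positive for finite `y`.
#' @export
alr_inverse <- function(y, base) {
  if (!is.numeric(y) || anyNA(y) || any(!is.finite(y))) {
    stop("`y` must be a finite numeric vector of log-ratios", call. = FALSE)
  }
  Q <- length(y) + 1L
  base <- check_base(base, Q)
  full <- numeric(Q)
  full[-base] <- y          # base taxon has implicit log-ratio 0
  shift <- max(full)
  e <- exp(full - shift)
  z <- e / sum(e)
  z
}

check_base <- function(base, Q) {
  if (length(base) != 1L || is.na(base) || base < 1 || base > Q ||
      base != round(base)) {
    stop(sprintf("`base` must be a single taxon index in 1..%d", Q),
         call. = FALSE)
  }
  as.integer(base)
}

# Row-wise helpers over matrices (samples as rows).
alr_rows <- function(Z, base) {
  t(apply(Z, 1, alr, base = base))
}

alr_inverse_rows <- function(Y, base) {
  t(apply(Y, 1, alr_inverse, base = base))
}

#' Perturb a count table to remove zeros
#'
#' Adds a constant `rho` to every entry of the count table so that all
#' entries are strictly positive and log-ratios are defined. The default
#' `rho = 0.5` is a conventional choice; diversity estimates can depend
#' noticeably on `rho` near zero, so the value should be reported and, when in
#' doubt, scanned (see [sensitivity_scan()]).
#'
#' @param counts Sample-by-taxon count matrix or data frame.
#' @param rho Perturbation in `(0, 1]`. Values of exactly 1 are accepted with
#'   a warning (useful for sensitivity comparisons); `rho <= 0` is an error.
#' @return A numeric matrix of strictly positive perturbed counts, with a
#'   `"rho"` attribute recording the perturbation used.
#' @export
perturb <- function(counts, rho = 0.5) {
  W <- as_count_matrix(counts)
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) || rho <= 0) {
    stop("`rho` must be a single positive number", call. = FALSE)
  }
  if (rho > 1) {
    stop("`rho` must be at most 1", call. = FALSE)
  }
  if (rho == 1) {
    warning("rho = 1 is at the boundary of the recommended (0, 1) range",
            call. = FALSE)
  }
  W_rho <- W + rho
  attr(W_rho, "rho") <- rho
  W_rho
}

#' Choose a base taxon for the log-ratio transform
#'
#' Returns the most abundant taxon (largest total count) among taxa observed
#' in every sample. Because the sensitivity of a log-ratio to its denominator
#' scales as `1/z_d`, a consistently abundant denominator keeps estimates
#' stable. If no taxon is present in all samples, falls back to the taxon
#' with the largest total count; ties are broken by the lowest taxon index.
#'
#' @param counts Sample-by-taxon count matrix or data frame.
#' @return Integer index of the chosen base taxon (with the taxon name,
#'   if any, as the `"taxon"` attribute).
#' @export
choose_base_taxon <- function(counts) {
  W <- as_count_matrix(counts)
  totals <- colSums(W)
  if (all(totals == 0)) {
    stop("cannot choose a base taxon: the count table is all zeros",
         call. = FALSE)
  }
  everywhere <- colSums(W > 0) == nrow(W)
  candidates <- if (any(everywhere)) which(everywhere) else seq_along(totals)
  d <- candidates[which.max(totals[candidates])]  # which.max = lowest index on ties
  d <- as.integer(d)
  attr(d, "taxon") <- colnames(W)[d]
  d
}
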
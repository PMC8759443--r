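#' Read a sample-by-taxon count table
#'
#' Reads a TSV or CSV file (delimiter sniffed from the extension, `.csv`
#' means comma) whose header row holds taxon names and whose first column
#' holds sample identifiers. Entries must be nonnegative integers. A table
#' stored taxa-as-rows is only accepted through the explicit
#' `orientation = "taxa"` flag - orientation is never guessed.
#'
#' @param path Path to the file.
#' @param orientation `"samples"` (rows are samples, default) or `"taxa"`
#'   (rows are taxa; the table is transposed after reading).
#' @return A named integer matrix, samples as rows.
#' @export
read_count_table <- function(path, orientation = c("samples", "taxa")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE)
  if (nrow(d) == 0 || ncol(d) < 2) {
    stop(sprintf("count table %s is empty or has no taxon columns", path),
         call. = FALSE)
  }
  ids <- as.character(d[[1]])
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate identifiers in %s: %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  M <- as.matrix(d[, -1])
  if (!is.numeric(M)) {
    stop(sprintf("non-numeric entries in count table %s", path), call. = FALSE)
  }
  rownames(M) <- ids
  if (anyNA(M) || any(M < 0) || any(M != round(M))) {
    bad <- which(is.na(M) | M < 0 | M != round(M), arr.ind = TRUE)[1, ]
    stop(sprintf("invalid count at row '%s', column '%s' of %s: entries must be nonnegative integers",
                 rownames(M)[bad[1]], colnames(M)[bad[2]], path), call. = FALSE)
  }
  if (orientation == "taxa") M <- t(M)
  storage.mode(M) <- "integer"
  M
}

#' Write a count table
#'
#' Inverse of [read_count_table()]: samples as rows, first column `sample`.
#'
#' @param counts Count matrix.
#' @param path Output path (`.csv` writes comma-separated, else tab).
#' @export
write_count_table <- function(counts, path) {
  W <- as_count_matrix(counts)
  d <- tibble::as_tibble(W, rownames = "sample")
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(d, path, delim = delim)
  invisible(path)
}

#' Read a covariate table and build a design matrix
#'
#' Reads a TSV/CSV keyed by sample identifier (first column), aligns rows to
#' the count table by identifier (not by file order), expands categorical
#' columns to treatment-coded indicators (first level as reference), and
#' prepends an intercept unless `no_intercept`.
#'
#' @param path Path to the covariate file.
#' @param counts The count matrix the design must align with.
#' @param no_intercept Suppress the intercept column?
#' @return A numeric design matrix with one row per count-table sample.
#' @export
read_covariates <- function(path, counts, no_intercept = FALSE) {
  W <- as_count_matrix(counts)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE)
  ids <- as.character(d[[1]])
  missing <- setdiff(rownames(W), ids)
  if (length(missing) > 0) {
    stop(sprintf("samples present in counts but missing covariates: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  d <- d[match(rownames(W), ids), -1, drop = FALSE]
  d <- as.data.frame(lapply(d, function(col) {
    if (is.character(col) || is.logical(col)) factor(col) else col
  }))
  fml <- if (no_intercept) ~ . - 1 else ~ .
  X <- stats::model.matrix(fml, data = d)
  rownames(X) <- rownames(W)
  X
}

#' Run the full estimation pipeline from files to files
#'
#' Reads the count (and optional covariate) tables, runs [netdiv()], and
#' writes: `alpha_diversity.tsv` (long table with standard errors),
#' `beta_<index>.tsv` (square matrices), `profiles.tsv` (sample-to-profile
#' map), `fit.json` (gamma, sigma, diagnostics) and `manifest.json` (every
#' flag, seed and package version needed to reproduce the run).
#'
#' @param counts_path Path to the count table.
#' @param covariates_path Optional path to the covariate table.
#' @param out_dir Output directory (created if absent).
#' @param orientation Orientation of the count file (see
#'   [read_count_table()]).
#' @param no_intercept Passed to [read_covariates()].
#' @inheritParams netdiv
#' @param quiet Suppress progress messages?
#' @return Invisibly, a named list of output paths.
#' @export
run_pipeline <- function(counts_path, covariates_path = NULL, out_dir,
                         orientation = "samples", no_intercept = FALSE,
                         indices = c("shannon", "simpson", "bray_curtis",
                                     "euclidean"),
                         base_taxon = NULL, rho = 0.5,
                         variance = "parametric", b_reps = 5L, n_sub = NULL,
                         mh = mh_config(), em = em_config(), seed = 1L,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  W <- stage("read-counts", read_count_table(counts_path, orientation))
  X <- if (!is.null(covariates_path)) {
    stage("read-covariates", read_covariates(covariates_path, W, no_intercept))
  }
  say(sprintf("fitting %d samples x %d taxa", nrow(W), ncol(W)))
  est <- stage("fit", netdiv(W, X, indices = indices, base_taxon = base_taxon,
                             rho = rho, variance = variance, b_reps = b_reps,
                             n_sub = n_sub, mh = mh, em = em, seed = seed))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  if (!is.null(est$alpha)) {
    paths$alpha <- file.path(out_dir, "alpha_diversity.tsv")
    readr::write_tsv(est$alpha, paths$alpha)
  }
  for (ix in names(est$beta)) {
    p <- file.path(out_dir, paste0("beta_", ix, ".tsv"))
    readr::write_tsv(tibble::as_tibble(est$beta[[ix]], rownames = "sample"), p)
    paths[[paste0("beta_", ix)]] <- p
  }
  paths$profiles <- file.path(out_dir, "profiles.tsv")
  readr::write_tsv(tibble::tibble(sample = est$compositions$labels,
                                  profile = est$compositions$profile),
                   paths$profiles)
  paths$fit <- file.path(out_dir, "fit.json")
  jsonlite::write_json(list(gamma = est$fit$gamma, sigma = est$fit$sigma,
                            base_taxon = est$fit$base,
                            diagnostics = est$fit$trace),
                       paths$fit, digits = NA)
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(
    package = "netdiv",
    version = as.character(utils::packageVersion("netdiv")),
    counts = counts_path, covariates = covariates_path,
    orientation = orientation, no_intercept = no_intercept,
    indices = indices, base_taxon = est$fit$base, rho = rho,
    variance = variance, b_reps = b_reps, n_sub = n_sub,
    mh = unclass(mh), em = unclass(em), seed = seed
  ), paths$manifest, auto_unbox = TRUE, null = "null", digits = NA)
  say(sprintf("wrote %d output files to %s", length(paths), out_dir))
  invisible(paths)
}
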
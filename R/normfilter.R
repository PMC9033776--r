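#' Filter genes by minimum count support
#'
#' Retains exactly the genes whose count is strictly greater than
#' `min_count` in at least `min_samples` samples (set `strict = FALSE` for
#' a `>=` rule). Gene order is preserved.
#'
#' @param counts integer matrix, genes x samples, with row and column names.
#' @param min_count count threshold (default 15; strict `>` comparison).
#' @param min_samples minimum number of samples passing the threshold.
#' @param strict use strict inequality (`> min_count`) when `TRUE`.
#' @return the filtered count matrix.
#' @export
filter_low_expression <- function(counts, min_count = 15L, min_samples = 2L,
                                  strict = TRUE) {
  stopifnot(is.matrix(counts), nrow(counts) > 0L)
  if (min_samples > ncol(counts))
    stop("min_samples exceeds the number of samples")
  pass <- if (strict) counts > min_count else counts >= min_count
  counts[rowSums(pass) >= min_samples, , drop = FALSE]
}

#' TMM normalization factors
#'
#' Per-sample scaling factors from the trimmed mean of M-values: trimmed
#' (30% on log-ratios, 5% on average abundance), precision-weighted means
#' of gene-wise log2 relative-abundance ratios against a reference sample
#' chosen by upper-quartile proximity, rescaled to geometric mean 1.
#' Computation is delegated to `edgeR::calcNormFactors`.
#'
#' @param counts integer count matrix, genes x samples (>= 2 samples, each
#'   with a positive total).
#' @param logratio_trim trim fraction on the M-values.
#' @param abs_trim trim fraction on average log abundance.
#' @return named numeric factors with attributes `lib_size` (raw column
#'   totals) and `effective_lib_size` (`lib_size * factor`).
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, abs_trim = 0.05) {
  stopifnot(is.matrix(counts))
  if (ncol(counts) < 2L) stop("TMM needs at least two samples")
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("every sample must have a positive total count")
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              logratioTrim = logratio_trim,
                              sumTrim = abs_trim)
  f <- stats::setNames(as.numeric(f), colnames(counts))
  attr(f, "lib_size") <- lib
  attr(f, "effective_lib_size") <- lib * f
  f
}

#' Log2 counts-per-million
#'
#' `log2((count + prior_count) / (effective_libsize + 1) * 1e6)`, with the
#' effective library size `colSums(counts) * factor`.
#'
#' @param counts count matrix, genes x samples.
#' @param factors normalization factors from [tmm_factors()], or `NULL` for
#'   unit factors.
#' @param prior_count nonnegative prior added to each count.
#' @return real matrix on the log2-CPM scale, with attributes
#'   `prior_count` and `effective_lib_size`.
#' @export
log_cpm <- function(counts, factors = NULL, prior_count = 0.5) {
  stopifnot(is.matrix(counts))
  if (prior_count < 0) stop("prior_count must be nonnegative")
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  if (length(factors) != ncol(counts))
    stop("factors must align with the samples")
  eff <- colSums(counts) * as.numeric(factors)
  out <- log2(sweep(counts + prior_count, 2L, (eff + 1) / 1e6, "/"))
  attr(out, "prior_count") <- prior_count
  attr(out, "effective_lib_size") <- eff
  out
}
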
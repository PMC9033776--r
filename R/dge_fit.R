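#' Fit the full moderated differential-expression model
#'
#' One-call pipeline for the two-factor perturbation design: count
#' filtering (strictly more than `min_count` reads in at least
#' `min_samples` samples), TMM normalization, log2-CPM conversion,
#' voom-type precision weights, per-gene weighted least squares on the
#' cell-means group design, the standard contrasts, and empirical-Bayes
#' variance moderation with BH FDR control.
#'
#' @param counts raw integer count matrix, genes x samples.
#' @param samples sample sheet with `diagnosis` and `treatment` columns.
#' @param min_count,min_samples,strict filtering rule, see
#'   [filter_low_expression()].
#' @param prior_count prior for the log2-CPM transform.
#' @param span lowess span for the mean-variance trend.
#' @param prior_df optional forced prior degrees of freedom, see
#'   [moderate_statistics()].
#' @return object of class `dge_fit` extending `contrast_fit`, carrying in
#'   addition the filtered counts, normalization factors, log-expression,
#'   weights, mean-variance trend and the design/contrast matrices.
#' @seealso [synergy()] for the additive/synergistic decomposition.
#' @export
dge_fit <- function(counts, samples, min_count = 15L, min_samples = 2L,
                    strict = TRUE, prior_count = 0.5, span = 0.5,
                    prior_df = NULL) {
  counts <- filter_low_expression(counts, min_count, min_samples,
                                  strict = strict)
  if (nrow(counts) == 0L) stop("no genes pass the expression filter")
  factors <- tmm_factors(counts)
  logexpr <- log_cpm(counts, factors, prior_count = prior_count)
  des <- build_design(samples)
  vw <- mean_variance_weights(logexpr, des$design, span = span,
                              lib_size = attr(factors, "effective_lib_size"))
  fit <- fit_contrasts(logexpr, vw$weights, des$design, des$contrasts)
  fit <- moderate_statistics(fit, prior_df = prior_df)
  fit$counts <- counts
  fit$norm_factors <- factors
  fit$logexpr <- logexpr
  fit$trend <- vw$trend
  fit$samples <- samples
  class(fit) <- c("dge_fit", class(fit))
  fit
}

#' @export
print.dge_fit <- function(x, ...) {
  cat("Moderated differential-expression fit\n")
  cat(sprintf("  %d genes x %d samples; groups: %s\n",
              nrow(x$coefficients), nrow(x$design),
              paste(colnames(x$design), collapse = ", ")))
  cat(sprintf("  contrasts: %s\n", paste(colnames(x$contrasts), collapse = ", ")))
  cat(sprintf("  prior df d0 = %.3g, prior variance s0^2 = %.3g\n",
              x$d0, x$s0_2))
  invisible(x)
}

#' @export
summary.dge_fit <- function(object, fdr = 0.05, ...) {
  de <- colSums(object$q <= fdr)
  out <- data.frame(contrast = colnames(object$q),
                    n_de = as.integer(de),
                    fraction = de / nrow(object$q),
                    row.names = NULL)
  attr(out, "fdr") <- fdr
  class(out) <- c("summary.dge_fit", "data.frame")
  out
}

#' @export
print.summary.dge_fit <- function(x, ...) {
  cat(sprintf("Genes at FDR <= %g per contrast:\n", attr(x, "fdr")))
  print.data.frame(x, digits = 3)
  invisible(x)
}

#' @export
coef.dge_fit <- function(object, ...) object$coefficients

#' @export
fitted.dge_fit <- function(object, ...)
  object$group_coefficients %*% t(object$design)

#' @export
residuals.dge_fit <- function(object, ...)
  object$logexpr - fitted.dge_fit(object)

#' Plot the fitted mean-variance trend
#'
#' Scatter of square-root residual standard deviation against average
#' log2-CPM with the lowess trend used for the precision weights.
#'
#' @param x a `dge_fit` object.
#' @param ... passed to `plot`.
#' @export
plot.dge_fit <- function(x, ...) {
  sx <- rowMeans(x$logexpr)
  sy <- sqrt(x$sigma)
  graphics::plot(sx, sy, pch = 16, cex = 0.3, col = "grey40",
                 xlab = "average log2-CPM",
                 ylab = expression(sqrt(sigma[g])), ...)
  graphics::lines(x$trend$x, x$trend$y, col = "red", lwd = 2)
  invisible(x)
}

#' Top-ranked genes for one contrast
#'
#' @param fit a moderated `contrast_fit` or `dge_fit`.
#' @param contrast contrast name.
#' @param n number of genes to return (by p-value).
#' @return data.frame with gene, logFC, t, p and q columns.
#' @export
top_genes <- function(fit, contrast = "SYNERGY", n = 10L) {
  stopifnot(isTRUE(fit$moderated), contrast %in% colnames(fit$coefficients))
  ord <- order(fit$p[, contrast])[seq_len(min(n, nrow(fit$p)))]
  data.frame(gene = rownames(fit$coefficients)[ord],
             logFC = fit$coefficients[ord, contrast],
             t = fit$t[ord, contrast],
             p = fit$p[ord, contrast],
             q = fit$q[ord, contrast],
             row.names = NULL)
}
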
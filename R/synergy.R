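contrast_stats <- function(fit, cvec) {
  # cvec named over canonical group levels; restrict to the fit's design
  lev <- colnames(fit$design)
  if (!all(names(cvec)[cvec != 0] %in% lev))
    stop("contrast references a group level missing from the fit")
  co <- cvec[lev]
  beta <- drop(fit$group_coefficients %*% co)
  u <- sqrt(apply(fit$cov_unscaled, 3L, function(V) drop(t(co) %*% V %*% co)))
  out <- list(beta = beta, u = u)
  if (isTRUE(fit$moderated)) {
    out$se <- u * sqrt(fit$s2_post)
    out$t <- beta / out$se
    out$p <- 2 * stats::pt(-abs(out$t), df = fit$df_total)
    out$q <- adjust_fdr(out$p)
  }
  out
}

#' Additive-effect model
#'
#' The expected additive log2 fold-change, modeled as the sum of the two
#' single-perturbation comparisons `(SZ vs ctrl) + (JQ1 vs ctrl)`. It is
#' evaluated as the single sum-contrast `SZ_VEH + CTRL_JQ - 2 CTRL_VEH`,
#' so its standard error is the proper contrast SE
#' `sqrt(c' (X'WX)^-1 c) * s_post`.
#'
#' @param fit a moderated `contrast_fit`/`dge_fit` on the four-group design.
#' @return data.frame with `gene`, `A` (additive log2FC) and `SE`.
#' @export
additive_model <- function(fit) {
  stopifnot(inherits(fit, "contrast_fit"))
  cs <- contrast_stats(fit, c(CTRL_VEH = -2, SZ_VEH = 1, CTRL_JQ = 1, SZ_JQ = 0))
  data.frame(gene = rownames(fit$coefficients), A = cs$beta,
             SE = if (is.null(cs$se)) cs$u * fit$sigma else cs$se,
             row.names = NULL)
}

#' Synergistic interaction contrast
#'
#' The synergistic log2 fold-change: the combinatorial comparison minus
#' the additive prediction, `(SZ+JQ vs ctrl) - (JQ vs ctrl) - (SZ vs
#' ctrl)`, evaluated as the single interaction contrast
#' `SZ_JQ - SZ_VEH - CTRL_JQ + CTRL_VEH` with moderated statistics.
#'
#' @param fit a moderated `contrast_fit`/`dge_fit` on the four-group design.
#' @return data.frame with `gene`, `S`, `SE`, `t`, `p`, `q`.
#' @export
synergy_contrast <- function(fit) {
  stopifnot(inherits(fit, "contrast_fit"), isTRUE(fit$moderated))
  cs <- contrast_stats(fit, c(CTRL_VEH = 1, SZ_VEH = -1, CTRL_JQ = -1, SZ_JQ = 1))
  data.frame(gene = rownames(fit$coefficients), S = cs$beta, SE = cs$se,
             t = cs$t, p = cs$p, q = cs$q, row.names = NULL)
}

#' Additive/synergistic decomposition with SE-threshold categories
#'
#' Builds the per-gene synergy table: additive log2FC `A`, combinatorial
#' log2FC `C` (SZ+JQ1 vs ctrl), synergistic log2FC `S = C - A` (the
#' interaction contrast), its moderated SE, the global threshold `tau`
#' (mean of the per-gene synergy SEs) and the category labels from
#' [classify_synergy()].
#'
#' @param fit a moderated `contrast_fit`/`dge_fit` on the four-group design.
#' @param tau global threshold; defaults to the mean synergy-contrast SE.
#' @return data.frame of class `synergy_table` with columns `gene`, `A`,
#'   `C`, `S`, `SE`, `t`, `p`, `q`, `category` and attribute `tau`.
#' @export
synergy <- function(fit, tau = NULL) {
  stopifnot(inherits(fit, "contrast_fit"), isTRUE(fit$moderated))
  add <- additive_model(fit)
  syn <- synergy_contrast(fit)
  comb <- contrast_stats(fit, c(CTRL_VEH = -1, SZ_VEH = 0, CTRL_JQ = 0, SZ_JQ = 1))
  tab <- data.frame(gene = add$gene, A = add$A, C = comb$beta, S = syn$S,
                    SE = syn$SE, t = syn$t, p = syn$p, q = syn$q,
                    row.names = NULL)
  if (is.null(tau)) tau <- mean(tab$SE)
  attr(tab, "tau") <- tau
  class(tab) <- c("synergy_table", "data.frame")
  classify_synergy(tab, tau = tau)
}

#' Classify genes into synergy categories
#'
#' A gene shows positive synergy if `S > tau` and negative synergy if
#' `S < -tau`, with `tau` the global threshold (by default the mean of the
#' per-gene synergy-contrast SEs — the average standard error across all
#' genes). A positive-synergy gene whose additive prediction has the same
#' or no direction (`A >= 0`) is `more_up`; a negative-synergy gene with
#' `A <= 0` is `more_down`; every other gene is `as_predicted`.
#'
#' @param table a `synergy_table` (or data.frame with `S` and `A`).
#' @param tau positive global threshold.
#' @return the table with a `category` factor column.
#' @export
classify_synergy <- function(table, tau = attr(table, "tau")) {
  stopifnot(all(c("S", "A") %in% names(table)))
  if (is.null(tau) || !is.finite(tau) || tau <= 0)
    stop("tau must be a positive number")
  category <- rep("as_predicted", nrow(table))
  category[table$S > tau & table$A >= 0] <- "more_up"
  category[table$S < -tau & table$A <= 0] <- "more_down"
  table$category <- factor(category,
                           levels = c("more_down", "more_up", "as_predicted"))
  attr(table, "tau") <- tau
  table
}

#' Summarize synergy categories
#'
#' Per-category counts and percentages of all classified genes (rounded to
#' one decimal), plus the total count of "more" genes (more_down +
#' more_up).
#'
#' @param table a classified `synergy_table`, or any data.frame/factor with
#'   a `category` column on the levels more_down/more_up/as_predicted.
#' @return data.frame with `category`, `count`, `percent`; attribute
#'   `total_more` holds the combined more_down + more_up count.
#' @export
summarize_synergy <- function(table) {
  category <- if (is.data.frame(table)) table$category else table
  stopifnot(!is.null(category))
  category <- factor(category, levels = c("more_down", "more_up", "as_predicted"))
  n <- table(category)
  total <- sum(n)
  out <- data.frame(category = names(n), count = as.integer(n),
                    percent = round(100 * as.integer(n) / total, 1),
                    row.names = NULL)
  attr(out, "total_more") <- sum(n[c("more_down", "more_up")])
  out
}

#' @export
print.synergy_table <- function(x, ...) {
  cat(sprintf("Synergy table: %d genes, tau = %.4g\n", nrow(x),
              attr(x, "tau")))
  s <- summarize_synergy(x)
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s %6d (%.1f%%)\n", s$category[i], s$count[i],
                s$percent[i]))
  cat(sprintf("  total 'more' genes: %d\n", attr(s, "total_more")))
  invisible(x)
}

#' @export
summary.synergy_table <- function(object, ...) summarize_synergy(object)

#' Pie chart of synergy categories
#'
#' @param x a classified `synergy_table`.
#' @param ... passed to `pie`.
#' @export
plot.synergy_table <- function(x, ...) {
  s <- summarize_synergy(x)
  graphics::pie(s$count,
                labels = sprintf("%s (%.1f%%)", s$category, s$percent),
                col = c("steelblue", "firebrick", "grey80"), ...)
  invisible(x)
}

#' Row/column orderings for clustered heatmaps
#'
#' Hierarchical clustering (Euclidean distance, complete linkage) of rows
#' and columns. When the number of rows exceeds `max_rows`, rows are first
#' pre-aggregated with k-means (fixed seed) and the dendrogram is built on
#' the `k` cluster centers.
#'
#' @param mat finite numeric matrix (e.g. genes x contrasts of t
#'   statistics or log2FCs).
#' @param max_rows pre-aggregation trigger.
#' @param k number of k-means clusters when aggregating.
#' @param seed seed for the k-means step.
#' @return list with `row_order` (ordering of rows, or of cluster centers
#'   when aggregated), `col_order`, `row_clusters` (k-means assignment or
#'   `NULL`) and `aggregated` (the matrix that was clustered).
#' @export
cluster_for_heatmap <- function(mat, max_rows = 1000L, k = 100L, seed = 1L) {
  stopifnot(is.matrix(mat), all(is.finite(mat)))
  row_clusters <- NULL
  x <- mat
  if (nrow(mat) > max_rows) {
    if (k >= nrow(mat)) stop("k must be smaller than the number of rows")
    set.seed(seed)
    km <- stats::kmeans(mat, centers = k, iter.max = 100L, nstart = 5L)
    row_clusters <- km$cluster
    x <- km$centers
  }
  row_order <- stats::hclust(stats::dist(x), method = "complete")$order
  col_order <- if (ncol(mat) >= 2L)
    stats::hclust(stats::dist(t(mat)), method = "complete")$order
  else 1L
  list(row_order = row_order, col_order = col_order,
       row_clusters = row_clusters, aggregated = x)
}
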
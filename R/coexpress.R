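unsigned_adjacency <- function(expr, power = 7) {
  if (any(apply(expr, 1L, stats::sd) == 0)) stop("constant gene rows")
  a <- abs(stats::cor(t(expr)))^power
  diag(a) <- 0
  a
}

#' Scale-free topology fit across soft-thresholding powers
#'
#' For each candidate power beta, builds the unsigned adjacency
#' `|cor|^beta`, computes the connectivity `k_i = sum_j a_ij` and the
#' signed R^2 of the `log10(freq)` vs `log10(k)` regression over binned
#' connectivities (negated when the slope is positive, since scale-free
#' networks require a decreasing degree distribution).
#'
#' @param expr expression matrix, genes x samples (>= 20 genes).
#' @param powers candidate integer powers.
#' @param n_bins connectivity bins for the degree-distribution fit.
#' @return data.frame with `power`, `sft_r2` (signed), `slope`, `mean_k`.
#' @export
pick_soft_threshold <- function(expr, powers = 1:12, n_bins = 10L) {
  stopifnot(is.matrix(expr), nrow(expr) >= 20L)
  cors <- abs(stats::cor(t(expr)))
  if (any(!is.finite(cors))) stop("constant gene rows")
  diag(cors) <- 0
  out <- lapply(powers, function(b) {
    k <- rowSums(cors^b)
    brk <- seq(min(k), max(k), length.out = n_bins + 1L)
    bin <- cut(k, breaks = brk, include.lowest = TRUE)
    freq <- tabulate(bin, nbins = n_bins)
    kmid <- tapply(k, bin, mean)
    keep <- freq > 0 & kmid > 0
    r2 <- NA_real_; slope <- NA_real_
    if (sum(keep) >= 3L) {
      fit <- stats::lm(log10(freq[keep]) ~ log10(kmid[keep]))
      slope <- stats::coef(fit)[2L]
      r2 <- summary(fit)$r.squared
      if (slope > 0) r2 <- -r2
    }
    data.frame(power = b, sft_r2 = r2, slope = unname(slope), mean_k = mean(k))
  })
  do.call(rbind, out)
}

#' Topological overlap dissimilarity
#'
#' Builds the unsigned adjacency `a_ij = |cor(x_i, x_j)|^power`, the
#' topological overlap
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' (with `TOM_ii = 1`), and returns the dissimilarity `1 - TOM`.
#'
#' @param expr expression matrix, genes x samples, no constant rows.
#' @param power soft-thresholding power.
#' @return symmetric dissimilarity matrix in `[0, 1]` with zero diagonal.
#' @export
tom_dissimilarity <- function(expr, power = 7) {
  a <- unsigned_adjacency(expr, power)
  if (any(a < 0 | a > 1)) stop("adjacency outside [0, 1]")
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  d <- 1 - tom
  d <- (d + t(d)) / 2
  dimnames(d) <- list(rownames(expr), rownames(expr))
  d
}

MODULE_COLORS <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta")

#' Detect co-expression modules by static tree cut
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity with a
#' static cut at a fixed height on the dissimilarity scale (branches
#' merging below `cut_height` form clusters; on a noise network, where
#' every dissimilarity sits near 1, nothing merges below the cut and all
#' genes fall to grey). Clusters smaller than `min_module_size` are
#' assigned to the "grey" (unconnected) module; remaining clusters are
#' labeled with color names in decreasing size order.
#'
#' @param dissim symmetric dissimilarity matrix from [tom_dissimilarity()].
#' @param min_module_size smallest cluster kept as a module.
#' @param cut_height static cut height on the dissimilarity scale.
#' @return named character vector of module colors, one per gene.
#' @export
detect_modules <- function(dissim, min_module_size = 30L,
                           cut_height = 0.9) {
  stopifnot(is.matrix(dissim), isTRUE(all.equal(dissim, t(dissim))))
  genes <- rownames(dissim)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(dissim)))
  if (nrow(dissim) < min_module_size)
    return(stats::setNames(rep("grey", nrow(dissim)), genes))
  h <- stats::hclust(stats::as.dist(dissim), method = "average")
  h$height <- cummax(h$height)   # absorb floating-point tie jitter
  raw <- stats::cutree(h, h = cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_module_size]
  labels <- rep("grey", length(raw))
  if (length(keep)) {
    ord <- keep[order(-sizes[keep])]
    for (i in seq_along(ord))
      labels[raw == ord[i]] <- MODULE_COLORS[((i - 1L) %% length(MODULE_COLORS)) + 1L]
  }
  stats::setNames(labels, genes)
}

#' Module eigengene
#'
#' Leading principal-component score vector (over samples) of the
#' standardized in-module expression, scaled to unit norm, with its sign
#' chosen so the correlation with the module's mean expression profile is
#' nonnegative. A singleton module's eigengene is its standardized gene.
#'
#' @param expr expression matrix, genes x samples.
#' @param genes member gene ids (rownames of `expr`).
#' @return unit-norm numeric vector, one value per sample.
#' @export
module_eigengene <- function(expr, genes) {
  x <- expr[genes, , drop = FALSE]
  xs <- t(scale(t(x)))                      # per-gene standardization
  if (nrow(xs) == 1L) {
    v <- drop(xs)
  } else {
    v <- svd(xs, nu = 0L, nv = 1L)$v[, 1L]
  }
  v <- v / sqrt(sum(v^2))
  if (stats::cor(v, colMeans(xs)) < 0) v <- -v
  stats::setNames(v, colnames(expr))
}

#' Merge similar modules by eigengene correlation
#'
#' Computes module eigengenes and iteratively merges the pair of non-grey
#' modules whose eigengene dissimilarity `1 - cor(ME_a, ME_b)` is smallest
#' and below `merge_height`, recomputing eigengenes after each merge,
#' until no pair falls under the cutoff.
#'
#' @param expr expression matrix, genes x samples.
#' @param labels module colors from [detect_modules()].
#' @param merge_height eigengene-dissimilarity cutoff (0 disables merging).
#' @return list with `labels` (merged colors), `eigengenes` (samples x
#'   modules matrix, unit-norm columns, grey excluded) and
#'   `merge_history` (data.frame of merged pairs and their heights).
#' @export
merge_modules <- function(expr, labels, merge_height = 0.17) {
  mods <- setdiff(unique(labels), "grey")
  if (length(mods) == 0L) stop("no non-grey module to merge")
  history <- data.frame(from = character(), into = character(),
                        height = numeric(), stringsAsFactors = FALSE)
  repeat {
    me <- vapply(mods, function(m) module_eigengene(expr, names(labels)[labels == m]),
                 numeric(ncol(expr)))
    if (length(mods) < 2L || merge_height <= 0) break
    d <- 1 - stats::cor(me)
    diag(d) <- Inf
    idx <- which(d == min(d), arr.ind = TRUE)[1L, ]
    if (d[idx[1L], idx[2L]] >= merge_height) break
    a <- mods[idx[1L]]; b <- mods[idx[2L]]
    sizes <- table(labels)
    into <- if (sizes[a] >= sizes[b]) a else b
    from <- if (into == a) b else a
    labels[labels == from] <- into
    history <- rbind(history,
                     data.frame(from = from, into = into,
                                height = d[idx[1L], idx[2L]]))
    mods <- setdiff(unique(labels), "grey")
  }
  rownames(me) <- colnames(expr)
  list(labels = labels, eigengenes = me, merge_history = history)
}

#' Filter module members by eigengene-membership significance
#'
#' Recomputes each module's eigengene and reassigns to grey the members
#' whose correlation with it (module membership, kME) is not significant
#' at level `alpha` (two-sided Student test on `n - 2` df). Two passes are
#' run so the eigengene sharpens after the first removal. With few samples
#' the null distribution of a gene-eigengene correlation is wide, so a
#' strict default level is used to keep spurious members out of modules.
#'
#' @param expr expression matrix, genes x samples.
#' @param labels module colors.
#' @param alpha significance level for module membership.
#' @return cleaned module colors (modules reduced below 2 genes go grey).
#' @export
filter_module_membership <- function(expr, labels, alpha = 0.001) {
  n <- ncol(expr)
  tcrit <- stats::qt(1 - alpha / 2, n - 2)
  rcrit <- sqrt(tcrit^2 / (n - 2 + tcrit^2))
  for (pass in 1:2) {
    for (m in setdiff(unique(labels), "grey")) {
      g <- names(labels)[labels == m]
      if (length(g) < 2L) { labels[g] <- "grey"; next }
      me <- module_eigengene(expr, g)
      kme <- as.vector(stats::cor(t(expr[g, , drop = FALSE]), me))
      labels[g[abs(kme) < rcrit]] <- "grey"
    }
  }
  labels
}

#' Module-trait association by weighted Pearson correlation
#'
#' Weighted Pearson correlation between each module eigengene and each
#' trait (one-hot group indicators), with the Student asymptotic p-value
#' `t = r sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom
#' (n = number of samples), two-sided. Uniform weights reduce to the
#' ordinary Pearson correlation.
#'
#' @param eigengenes samples x modules matrix.
#' @param traits samples x traits numeric matrix (e.g. one-hot groups).
#' @param weights per-sample nonnegative weights (default uniform).
#' @return list of class `trait_association` with matrices `r` and `p`
#'   (modules x traits).
#' @export
module_trait_association <- function(eigengenes, traits, weights = NULL) {
  eigengenes <- as.matrix(eigengenes); traits <- as.matrix(traits)
  n <- nrow(eigengenes)
  stopifnot(n >= 3L, nrow(traits) == n)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  wcor <- function(x, y) {
    mx <- sum(w * x); my <- sum(w * y)
    vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
    if (vx == 0 || vy == 0) stop("zero-variance eigengene or trait")
    sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
  }
  r <- matrix(NA_real_, ncol(eigengenes), ncol(traits),
              dimnames = list(colnames(eigengenes), colnames(traits)))
  for (i in seq_len(ncol(eigengenes)))
    for (j in seq_len(ncol(traits)))
      r[i, j] <- wcor(eigengenes[, i], traits[, j])
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  structure(list(r = r, p = p, n = n), class = "trait_association")
}

#' @export
print.trait_association <- function(x, ...) {
  cat(sprintf("Module-trait association (%d samples)\n", x$n))
  cat("correlations:\n"); print(round(x$r, 2))
  cat("p-values:\n"); print(signif(x$p, 2))
  invisible(x)
}

#' Full co-expression module pipeline
#'
#' TOM dissimilarity at the given power, static-cut module detection,
#' eigengene merging and (optionally) module-trait association against
#' one-hot group indicators.
#'
#' @param expr expression matrix, genes x samples.
#' @param power soft-thresholding power (default 7).
#' @param merge_height eigengene merge cutoff (default 0.17).
#' @param min_module_size,cut_height see [detect_modules()].
#' @param kme_alpha membership-significance level for
#'   [filter_module_membership()]; `NULL` disables the cleanup.
#' @param covariates optional samples x covariates matrix; expression is
#'   residualized gene-wise on these before network construction.
#' @param traits optional samples x traits matrix for the association step.
#' @return list with `labels`, `eigengenes`, `merge_history`, `n_modules`
#'   (non-grey), `n_modules_total` (including grey when present) and
#'   `trait_association` (or `NULL`).
#' @export
coexpression_modules <- function(expr, power = 7, merge_height = 0.17,
                                 min_module_size = 30L, cut_height = 0.9,
                                 kme_alpha = 0.001, covariates = NULL,
                                 traits = NULL) {
  if (!is.null(covariates)) {
    X <- cbind(1, as.matrix(covariates))
    expr <- expr - t(X %*% qr.coef(qr(X), t(expr)))
  }
  d <- tom_dissimilarity(expr, power = power)
  labels <- detect_modules(d, min_module_size = min_module_size,
                           cut_height = cut_height)
  empty <- list(labels = labels, eigengenes = NULL, merge_history = NULL,
                n_modules = 0L, n_modules_total = 1L,
                trait_association = NULL)
  if (all(labels == "grey")) return(empty)
  merged <- merge_modules(expr, labels, merge_height = merge_height)
  labels <- merged$labels
  if (!is.null(kme_alpha)) {
    labels <- filter_module_membership(expr, labels, alpha = kme_alpha)
    if (all(labels == "grey")) { empty$labels <- labels; return(empty) }
  }
  mods <- setdiff(unique(labels), "grey")
  me <- vapply(mods,
               function(m) module_eigengene(expr, names(labels)[labels == m]),
               numeric(ncol(expr)))
  rownames(me) <- colnames(expr)
  assoc <- if (!is.null(traits)) module_trait_association(me, traits)
  list(labels = labels, eigengenes = me,
       merge_history = merged$merge_history, n_modules = length(mods),
       n_modules_total = length(mods) + as.integer(any(labels == "grey")),
       trait_association = assoc)
}
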
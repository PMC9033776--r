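#' Read a GMT gene-set file
#'
#' One set per tab-separated line: name, description, members. Duplicate
#' members within a set are removed; the description field is kept as the
#' set's category label.
#'
#' @param path GMT file path.
#' @return a `gene_set_collection`: list with `sets` (named list of member
#'   vectors), `category` (named character from the description field) and
#'   `source` (the file path).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("malformed GMT: line ", bad[1L], " has fewer than 3 fields")
  nm <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(nm)) stop("duplicate set names in GMT")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  category <- stats::setNames(vapply(fields, `[[`, character(1L), 2L), nm)
  structure(list(sets = sets, category = category, source = path),
            class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#'
#' @param collection a `gene_set_collection`.
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  desc <- collection$category
  if (is.null(desc)) desc <- stats::setNames(rep("na", length(collection$sets)),
                                             names(collection$sets))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, desc[[nm]], collection$sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("Gene-set collection: %d sets (%d categories)\n",
              length(x$sets), length(unique(x$category))))
  invisible(x)
}

#' Competitive gene-set enrichment with inter-gene correlation
#'
#' camera-style competitive test: per-gene moderated t statistics are
#' converted to normal-equivalent scores, and each set is compared against
#' the rest of the genome by a two-sample t statistic whose in-set variance
#' term is inflated by the variance-inflation factor
#' `VIF = 1 + (m - 1) * rho`, accounting for inter-gene correlation `rho`.
#'
#' @param gene_stats named numeric vector of per-gene moderated t
#'   statistics (one contrast).
#' @param sets a `gene_set_collection`.
#' @param inter_gene_cor assumed mean inter-gene correlation within sets.
#' @param df degrees of freedom of the moderated t statistics; when `NULL`
#'   the statistics are treated as normal scores already.
#' @return data.frame with set, category, effective size `m`, direction
#'   (Up/Down), `p` (two-sided) and BH `fdr`, ordered by p.
#' @export
camera_test <- function(gene_stats, sets, inter_gene_cor = 0.01, df = NULL) {
  stopifnot(inherits(sets, "gene_set_collection"),
            !is.null(names(gene_stats)))
  z <- if (is.null(df)) gene_stats
       else stats::qnorm(stats::pt(gene_stats, df = df, log.p = TRUE),
                         log.p = TRUE)
  G <- length(z)
  if (G < 4L) stop("need at least 4 genes in the universe")
  mean_all <- mean(z)
  var_all <- stats::var(z)

  res <- lapply(names(sets$sets), function(nm) {
    idx <- names(z) %in% sets$sets[[nm]]
    m <- sum(idx)
    m2 <- G - m
    if (m < 2L || m2 < 2L) {
      warning("skipping set '", nm, "' with fewer than 2 genes in or out")
      return(NULL)
    }
    vif <- 1 + (m - 1) * inter_gene_cor
    delta <- mean(z[idx]) - mean_all
    # pooled residual variance of the two-group decomposition
    var_pooled <- ((G - 1) * var_all - delta^2 * G * m / m2) / (G - 2)
    tstat <- delta * G / m2 / sqrt(var_pooled * (vif / m + 1 / m2))
    data.frame(set = nm, category = unname(sets$category[nm]), m = m,
               direction = if (delta > 0) "Up" else "Down",
               statistic = tstat,
               p = 2 * stats::pt(-abs(tstat), df = G - 2L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) stop("no testable sets")
  out$fdr <- adjust_fdr(out$p)
  out[order(out$p), , drop = FALSE]
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of a hit list against a background of
#' expressed genes: `P(X >= k)` with `N = |universe|`,
#' `K = |set ∩ universe|`, `n = |hits|`, `k = |hits ∩ set|`. Results are
#' BH-adjusted and ranked by `-log10(p)`.
#'
#' @param hits character vector of genes of interest (must be a subset of
#'   `universe`).
#' @param universe background of all expressed genes.
#' @param sets a `gene_set_collection`.
#' @return data.frame with set, category, `N`, `K`, `n`, `k`, `p`, `fdr`
#'   and `neg_log10_p`, ordered by decreasing `-log10(p)`.
#' @export
hypergeometric_ora <- function(hits, universe, sets) {
  stopifnot(inherits(sets, "gene_set_collection"))
  hits <- unique(hits); universe <- unique(universe)
  missing <- setdiff(hits, universe)
  if (length(missing))
    stop("hits not in the universe: ", paste(utils::head(missing, 5L),
                                             collapse = ", "))
  N <- length(universe)
  n <- length(hits)
  out <- do.call(rbind, lapply(names(sets$sets), function(nm) {
    members <- intersect(sets$sets[[nm]], universe)
    K <- length(members)
    k <- length(intersect(hits, members))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, category = unname(sets$category[nm]),
               N = N, K = K, n = n, k = k, p = p, stringsAsFactors = FALSE)
  }))
  out$fdr <- adjust_fdr(out$p)
  out$neg_log10_p <- -log10(out$p)
  out[order(-out$neg_log10_p), , drop = FALSE]
}
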
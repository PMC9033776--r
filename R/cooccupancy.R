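#' Define promoter regions around TSS coordinates
#'
#' Symmetric flank of `flank_bp` around each TSS in 0-based half-open
#' (BED) coordinates: `[tss - flank, tss + flank)`, with the start clamped
#' at 0. The flank is strand-invariant; strand is recorded.
#'
#' @param tss_table data.frame with columns `chrom`, `tss`, `strand`,
#'   `gene` (TSS as a 0-based point coordinate).
#' @param flank_bp nonnegative flank in bp (default 1000, i.e. +/- 1 kb).
#' @return data.frame with `chrom`, `start`, `end`, `id`, `strand`,
#'   `length_bp`; one region per TSS record.
#' @export
define_promoters <- function(tss_table, flank_bp = 1000L) {
  stopifnot(is.data.frame(tss_table),
            all(c("chrom", "tss", "strand", "gene") %in% names(tss_table)))
  if (flank_bp < 0) stop("flank_bp must be nonnegative")
  if (any(tss_table$tss < 0)) stop("TSS coordinates must be nonnegative")
  start <- pmax(tss_table$tss - flank_bp, 0L)
  end <- tss_table$tss + flank_bp
  data.frame(chrom = tss_table$chrom, start = as.integer(start),
             end = as.integer(end), id = tss_table$gene,
             strand = tss_table$strand,
             length_bp = as.integer(end - start),
             stringsAsFactors = FALSE)
}

#' Reads per kilobase per million (RPKM)
#'
#' `count * 1e9 / (length_bp * libsize)`.
#'
#' @param counts nonnegative region counts.
#' @param lengths_bp positive region lengths in bp.
#' @param libsize positive library size (total mapped reads).
#' @return RPKM vector.
#' @export
rpkm <- function(counts, lengths_bp, libsize) {
  if (any(lengths_bp <= 0)) stop("region lengths must be positive")
  if (any(libsize <= 0)) stop("library size must be positive")
  as.numeric(counts) * 1e9 / (as.numeric(lengths_bp) * as.numeric(libsize))
}

#' Spearman rank correlation of two occupancy signals
#'
#' Spearman rho with average (mid) ranks for ties and the two-sided
#' p-value from the large-sample t approximation
#' `t = rho sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param x,y equal-length numeric vectors (n >= 3), non-constant.
#' @return list with `rho`, `p` and `n`.
#' @export
rank_correlation <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3L) stop("x and y must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant vector")
  ct <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  list(rho = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Promoter co-occupancy correlation
#'
#' Converts two per-region raw count vectors (e.g. BRD4 and H2A.Zac
#' promoter reads) to RPKM and returns their Spearman rank correlation.
#'
#' @param counts_a,counts_b per-region counts for the two signals.
#' @param lengths_bp region lengths in bp.
#' @param libsize_a,libsize_b per-signal library sizes; default the column
#'   sums of the supplied counts.
#' @return list with `rho`, `p`, `n` and the two RPKM vectors.
#' @export
cooccupancy_correlation <- function(counts_a, counts_b, lengths_bp,
                                    libsize_a = sum(counts_a),
                                    libsize_b = sum(counts_b)) {
  ra <- rpkm(counts_a, lengths_bp, libsize_a)
  rb <- rpkm(counts_b, lengths_bp, libsize_b)
  c(rank_correlation(ra, rb), list(rpkm_a = ra, rpkm_b = rb))
}
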
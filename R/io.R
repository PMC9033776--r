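#' Write / read a count matrix as TSV
#'
#' Plain TSV with a `gene_id` first column and one column per sample.
#'
#' @param counts integer matrix with row and column names.
#' @param path file path.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1L]]
  m
}

#' Write / read a sample sheet as CSV
#'
#' Columns `sample_id`, `diagnosis`, `treatment`.
#'
#' @param samples sample sheet data.frame.
#' @param path file path.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.csv(samples[, c("sample_id", "diagnosis", "treatment")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write promoter regions as BED6
#'
#' 0-based half-open coordinates; score column set to 0.
#'
#' @param regions data.frame from [define_promoters()].
#' @param path file path.
#' @export
write_bed <- function(regions, path) {
  bed <- data.frame(regions$chrom, regions$start, regions$end,
                    regions$id, 0L, regions$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
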
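#' Read and write tab-separated tables
#'
#' Thin wrappers around readr with the column conventions used throughout
#' the package (TSV, header, no quoting).
#'
#' @param x data frame.
#' @param path file path.
#' @return `read_tsv_table` returns a tibble.
#' @export
write_tsv_table <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write intervals as BED4
#'
#' 0-based half-open intervals with the `name` column carrying a state or
#' category label.
#'
#' @param x tibble with columns chrom, start, end and a name column.
#' @param path file path.
#' @param name_col column written as the BED name field.
#' @export
write_bed <- function(x, path, name_col = "state") {
  bed <- data.frame(chrom = x$chrom, start = format(x$start, scientific = FALSE, trim = TRUE),
                    end = format(x$end, scientific = FALSE, trim = TRUE),
                    name = x[[name_col]])
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED4 file of labelled intervals
#'
#' @param path file path.
#' @param name_col name to give the fourth column.
#' @return tibble: chrom, start, end, `name_col`.
#' @export
read_bed <- function(path, name_col = "state") {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end", name_col),
                         colClasses = c("character", "numeric", "numeric", "character"))
  tibble::as_tibble(x)
}

#' Export a SNP table as minimal VCF 4.2
#'
#' Writes the parent-diagnostic SNPs with the lyc allele as REF and the pen
#' allele as ALT.
#'
#' @param snps SNP table (chrom, pos, ref_lyc, alt_pen).
#' @param path file path.
#' @export
write_snp_vcf <- function(snps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(snps) > 0) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                       snps$chrom, snps$pos, snps$ref_lyc, snps$alt_pen), con)
  }
  invisible(path)
}

#' Write / read a count matrix as wide TSV
#'
#' Features as rows (first column `feature`), samples as columns.
#'
#' @param mat features x samples matrix.
#' @param path file path.
#' @export
write_counts_tsv <- function(mat, path) {
  df <- data.frame(feature = rownames(mat), mat, check.names = FALSE)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}

#' Write size-resolved sRNA counts as long-form TSV
#'
#' @param sc a [sized_counts()] object.
#' @param path file path.
#' @export
write_sized_counts_tsv <- function(sc, path) {
  readr::write_tsv(sc$counts, path)
  invisible(path)
}
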
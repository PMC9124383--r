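TE_ORDERS <- c("EPRV", "helitron", "LTR", "TIR", "other")
FEATURE_CATEGORIES <- c("gene", "promoter", TE_ORDERS)
SIZE_CLASSES <- 20:25

#' Tile a genome into adjacent non-overlapping sRNA locus bins
#'
#' Each chromosome is sliced into `width`-bp adjacent non-overlapping bins
#' (default 200 bp); a shorter terminal bin is retained (and flagged) when
#' the chromosome length is not a multiple of the width.
#'
#' @param genome tibble (chrom, length).
#' @param width bin width in bp.
#' @return tibble of class bins: bin, chrom, start, end (0-based half-open),
#'   is_partial.
#' @export
make_bins <- function(genome, width = 200) {
  if (width <= 0) stop("width must be positive")
  if (any(genome$length <= 0)) stop("chromosome lengths must be positive")
  dplyr::bind_rows(lapply(seq_len(nrow(genome)), function(i) {
    L <- genome$length[i]
    ch <- genome$chrom[i]
    start <- seq(0, L - 1, by = width)
    end <- pmin(start + width, L)
    tibble::tibble(bin = sprintf("%s:%d-%d", ch, start, end),
                   chrom = ch, start = start, end = end,
                   is_partial = (end - start) < width)
  }))
}

#' Annotate bins against genomic features
#'
#' A bin carries a feature flag iff it overlaps that feature by at least one
#' base pair; flags are binary and a bin may carry several. Recognised
#' categories are `gene`, `promoter` and the transposable-element orders
#' `EPRV`, `helitron`, `LTR`, `TIR`, `other`.
#'
#' @param bins a bin table from [make_bins()].
#' @param features tibble (chrom, start, end, category), 0-based half-open.
#' @return `bins` with one logical column per category.
#' @export
annotate_bins <- function(bins, features) {
  unknown <- setdiff(unique(features$category), FEATURE_CATEGORIES)
  if (length(unknown) > 0) {
    stop("unknown feature category: ", paste(unknown, collapse = ", "))
  }
  out <- bins
  bin_gr <- GenomicRanges::GRanges(bins$chrom,
                                   IRanges::IRanges(bins$start + 1, bins$end))
  for (cat in FEATURE_CATEGORIES) {
    f <- features[features$category == cat, , drop = FALSE]
    flag <- rep(FALSE, nrow(bins))
    if (nrow(f) > 0) {
      f_gr <- GenomicRanges::GRanges(f$chrom, IRanges::IRanges(f$start + 1, f$end))
      flag[unique(S4Vectors::queryHits(
        GenomicRanges::findOverlaps(bin_gr, f_gr)))] <- TRUE
    }
    out[[cat]] <- flag
  }
  out
}

#' Derive promoter intervals from gene annotations
#'
#' Promoters are defined as the `width` bp immediately upstream of the
#' annotated gene start, strand-aware, clipped at chromosome bounds.
#'
#' @param genes tibble (chrom, start, end, strand) with strand "+" or "-".
#' @param genome genome length table (chrom, length).
#' @param width promoter width in bp.
#' @return tibble (chrom, start, end, category = "promoter").
#' @export
promoter_intervals <- function(genes, genome, width = 1000) {
  L <- stats::setNames(genome$length, genome$chrom)[genes$chrom]
  start <- ifelse(genes$strand == "-", genes$end, pmax(genes$start - width, 0))
  end <- ifelse(genes$strand == "-", pmin(genes$end + width, L), genes$start)
  keep <- end > start
  tibble::tibble(chrom = genes$chrom[keep], start = start[keep],
                 end = end[keep], category = "promoter")
}

#' Sized count container
#'
#' Bundles a per-(bin, sample) total count matrix with the long-form counts
#' resolved by read size for the 20--25 nt profile window. Totals may exceed
#' the column sums of the sized counts when reads outside the profile window
#' contribute to the totals only.
#'
#' @param counts long tibble (bin, sample, size, count), sizes 20--25 only.
#' @param totals matrix bins x samples of total assigned reads.
#' @return object of class `sized_counts`.
#' @export
sized_counts <- function(counts, totals) {
  stopifnot(all(counts$size %in% SIZE_CLASSES), all(counts$count >= 0),
            all(totals >= 0))
  by_bs <- tapply(counts$count,
                  list(factor(counts$bin, rownames(totals)),
                       factor(counts$sample, colnames(totals))),
                  sum, default = 0L)
  if (any(by_bs > totals + 1e-9)) {
    stop("size-resolved counts exceed the per-bin totals")
  }
  structure(list(counts = counts, totals = totals), class = "sized_counts")
}

#' Count sRNA read records into bins by 5' position and size
#'
#' Reads with lengths outside `length_window` (default 15--40 nt) are
#' discarded. Each surviving read is assigned to exactly one bin by its
#' 0-based 5' position, contributing to the bin/sample total; reads whose
#' length falls inside `profile_window` (default 20--25 nt) additionally
#' populate the size-resolved counts.
#'
#' @param reads tibble (chrom, pos, length, sample) with 0-based 5'
#'   positions.
#' @param bins bin table from [make_bins()].
#' @param length_window inclusive read-length retention window.
#' @param profile_window inclusive window of the size-resolved profile.
#' @return a [sized_counts()] object over all bins and samples seen.
#' @export
count_reads <- function(reads, bins, length_window = c(15, 40),
                        profile_window = c(20, 25)) {
  keep <- reads$length >= length_window[1] & reads$length <= length_window[2]
  r <- reads[keep, , drop = FALSE]
  samples <- sort(unique(reads$sample))
  totals <- matrix(0L, nrow(bins), length(samples),
                   dimnames = list(bins$bin, samples))
  sized <- list()
  for (ch in unique(r$chrom)) {
    b <- bins[bins$chrom == ch, , drop = FALSE]
    if (nrow(b) == 0) stop("reads on unknown chromosome: ", ch)
    rr <- r[r$chrom == ch, , drop = FALSE]
    if (any(rr$pos < 0 | rr$pos >= max(b$end))) {
      stop("read position outside chromosome ", ch)
    }
    idx <- findInterval(rr$pos, b$start)
    rr$bin <- b$bin[idx]
    tab <- tapply(rep(1L, nrow(rr)), list(factor(rr$bin, bins$bin), factor(rr$sample, samples)),
                  sum, default = 0L)
    totals <- totals + tab
    in_prof <- rr$length >= profile_window[1] & rr$length <= profile_window[2]
    rp <- rr[in_prof, , drop = FALSE]
    if (nrow(rp) > 0) {
      agg <- stats::aggregate(list(count = rep(1L, nrow(rp))),
                              by = list(bin = rp$bin, sample = rp$sample,
                                        size = rp$length),
                              FUN = sum)
      sized[[ch]] <- tibble::as_tibble(agg)
    }
  }
  counts <- if (length(sized)) dplyr::bind_rows(sized) else
    tibble::tibble(bin = character(), sample = character(),
                   size = integer(), count = integer())
  sized_counts(counts, totals)
}

#' Counts-per-million normalization
#'
#' Scales each sample's counts to reads per million using the per-sample
#' library totals.
#'
#' @param mat features x samples count matrix.
#' @param totals per-sample library sizes; defaults to the column sums.
#' @return matrix of CPM values.
#' @export
cpm_normalize <- function(mat, totals = colSums(mat)) {
  if (any(totals <= 0)) stop("library totals must be positive")
  sweep(mat, 2L, totals, "/") * 1e6
}
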
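#' Pairwise observed/expected overlap of DE feature sets
#'
#' For each ordered pair of samples the universe is the set of features
#' testable (class != NONE) in both; the expected shared count under
#' independence is `|A||B| / |U|` with A and B restricted to the universe,
#' and the reported ratio is observed / expected.
#'
#' @param de_sets named list of DE feature-id vectors (one per sample).
#' @param universes named list of testable feature-id vectors, same names.
#' @return tibble: sample_a, sample_b, observed, expected, ratio,
#'   universe_size (all ordered pairs including self-pairs).
#' @export
overlap_matrix <- function(de_sets, universes) {
  stopifnot(identical(names(de_sets), names(universes)))
  nm <- names(de_sets)
  rows <- list()
  for (a in nm) for (b in nm) {
    U <- intersect(universes[[a]], universes[[b]])
    if (length(U) == 0) stop("empty pairwise universe for ", a, " vs ", b)
    A <- intersect(de_sets[[a]], U)
    B <- intersect(de_sets[[b]], U)
    obs <- length(intersect(A, B))
    expd <- length(A) * length(B) / length(U)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      sample_a = a, sample_b = b, observed = obs, expected = expd,
      ratio = ifelse(expd > 0, obs / expd, NA_real_),
      universe_size = length(U))
  }
  dplyr::bind_rows(rows)
}

#' Feature-category enrichment of DE classes
#'
#' For the genome and for each annotation category, the percentage of that
#' category's testable bins (class != NONE) classified UP and DOWN, and
#' their ratio. Categories with no testable bins report NA rather than
#' erroring.
#'
#' @param de DE table (feature, class) on bins.
#' @param bins annotated bin table from [annotate_bins()] (or the generator).
#' @param categories flag columns to report; defaults to gene, promoter and
#'   the TE orders present in `bins`.
#' @return tibble: category, n_testable, pct_up, pct_down, up_down_ratio.
#' @export
feature_enrichment <- function(de, bins,
                               categories = intersect(FEATURE_CATEGORIES,
                                                      colnames(bins))) {
  cls <- de$class[match(bins$bin, de$feature)]
  testable <- !is.na(cls) & cls != "NONE"
  one <- function(name, sel) {
    idx <- testable & sel
    k <- sum(idx)
    if (k == 0) {
      return(tibble::tibble(category = name, n_testable = 0L,
                            pct_up = NA_real_, pct_down = NA_real_,
                            up_down_ratio = NA_real_))
    }
    up <- 100 * sum(cls[idx] == "UP") / k
    dn <- 100 * sum(cls[idx] == "DOWN") / k
    tibble::tibble(category = name, n_testable = k, pct_up = up, pct_down = dn,
                   up_down_ratio = ifelse(dn > 0, up / dn, NA_real_))
  }
  dplyr::bind_rows(c(list(one("genome", rep(TRUE, nrow(bins)))),
                     lapply(categories, function(cat) one(cat, bins[[cat]]))))
}

#' Size-class profile of a bin subset
#'
#' CPM-normalizes the size-resolved counts of one sample by its total
#' library size and sums them over a bin subset, returning one value per
#' read size 20--25 nt.
#'
#' @param sc a [sized_counts()] object.
#' @param bin_subset character vector of bin ids (non-empty).
#' @param sample sample name.
#' @return named numeric vector over sizes "20".."25".
#' @export
size_profile <- function(sc, bin_subset, sample) {
  if (length(bin_subset) == 0) stop("empty bin subset")
  if (!sample %in% colnames(sc$totals)) stop("unknown sample: ", sample)
  lib <- sum(sc$totals[, sample])
  if (lib <= 0) stop("sample has no reads")
  cc <- sc$counts[sc$counts$sample == sample & sc$counts$bin %in% bin_subset, ]
  out <- stats::setNames(numeric(length(SIZE_CLASSES)), SIZE_CLASSES)
  if (nrow(cc) > 0) {
    agg <- tapply(cc$count, factor(cc$size, SIZE_CLASSES), sum, default = 0)
    out[] <- as.numeric(agg) * 1e6 / lib
  }
  out
}

#' Cross-classification of hybrid and dcl2 sRNA locus classes
#'
#' Builds the 3x3 table of bins by hybrid class (UP / DOWN / NON_DE) against
#' dcl2 class (+D2SL / -D2SL / non-D2SL, i.e. UP / DOWN / NON_DE in the
#' dcl2-vs-WT contrast), restricted to bins carrying one of those three
#' classes in both contrasts ("in-between" bins are excluded). Each cell
#' reports its bin count, its normalized size profile in the chosen sample
#' summed over the cell's bins, and the EPRV read fraction (reads in
#' EPRV-flagged bins over all reads in the cell's bins, in that sample).
#'
#' @param de_hybrid,de_dcl2 DE tables on the same bin set.
#' @param sc a [sized_counts()] object.
#' @param bins annotated bin table with an `EPRV` flag column.
#' @param sample sample whose counts fill the size profiles and EPRV
#'   fractions.
#' @return list with `tab` (3x3 count matrix, hybrid rows x dcl2 columns)
#'   and `cells` (tibble: hybrid_class, dcl2_class, n, eprv_read_frac, and
#'   normalized profile columns p20..p25 summing to 1 where nonzero).
#' @export
crosstab_dcl2 <- function(de_hybrid, de_dcl2, sc, bins, sample) {
  common <- intersect(de_hybrid$feature, de_dcl2$feature)
  if (length(common) == 0) stop("the two DE tables share no bins")
  keep_classes <- c("UP", "DOWN", "NON_DE")
  ch <- de_hybrid$class[match(common, de_hybrid$feature)]
  cd <- de_dcl2$class[match(common, de_dcl2$feature)]
  use <- ch %in% keep_classes & cd %in% keep_classes
  common <- common[use]; ch <- ch[use]; cd <- cd[use]
  tab <- table(factor(ch, keep_classes), factor(cd, keep_classes))
  tab <- matrix(as.integer(tab), 3, 3, dimnames = list(hybrid = keep_classes,
                                                       dcl2 = keep_classes))
  eprv_bins <- bins$bin[bins$EPRV]
  cells <- list()
  for (i in keep_classes) for (j in keep_classes) {
    sel <- common[ch == i & cd == j]
    prof <- stats::setNames(rep(NA_real_, 6), paste0("p", SIZE_CLASSES))
    eprv_frac <- NA_real_
    if (length(sel) > 0) {
      p <- size_profile(sc, sel, sample)
      tot <- sum(p)
      prof[] <- if (tot > 0) p / tot else 0
      reads_all <- sum(sc$totals[sel, sample])
      reads_eprv <- sum(sc$totals[intersect(sel, eprv_bins), sample])
      eprv_frac <- if (reads_all > 0) reads_eprv / reads_all else 0
    }
    cells[[length(cells) + 1L]] <- tibble::tibble(
      hybrid_class = i, dcl2_class = j, n = length(sel),
      eprv_read_frac = eprv_frac, !!!as.list(prof))
  }
  list(tab = tab, cells = dplyr::bind_rows(cells))
}

#' Fisher's exact test for the overlap of two feature sets
#'
#' Two-tailed exact hypergeometric test (probability-mass rule, as in
#' `stats::fisher.test`) of whether two sets drawn from a common universe
#' share more members than expected; the conditional-MLE odds ratio is
#' reported.
#'
#' @param n_overlap size of the intersection.
#' @param n_a,n_b set sizes.
#' @param n_universe universe size.
#' @return list: odds_ratio, p_value, table (the underlying 2x2).
#' @export
fisher_overlap <- function(n_overlap, n_a, n_b, n_universe) {
  if (n_overlap > min(n_a, n_b) || max(n_a, n_b) > n_universe ||
      n_universe - n_a - n_b + n_overlap < 0 || n_overlap < 0) {
    stop("inconsistent overlap counts")
  }
  tab <- matrix(c(n_overlap, n_a - n_overlap,
                  n_b - n_overlap, n_universe - n_a - n_b + n_overlap),
                nrow = 2,
                dimnames = list(in_a = c("yes", "no"), in_b = c("yes", "no")))
  ft <- stats::fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value, table = tab)
}

#' Fold-change concordance between two contrasts
#'
#' Pearson correlation (two-sided p from the t approximation, via
#' `stats::cor.test`) of the log2 fold changes of features significantly DE
#' (FDR below `fdr_threshold`) in both tables.
#'
#' @param de_a,de_b DE tables sharing feature ids.
#' @param fdr_threshold significance cut for inclusion.
#' @return list: r, p_value, n.
#' @export
logfc_concordance <- function(de_a, de_b, fdr_threshold = 0.05) {
  common <- intersect(de_a$feature, de_b$feature)
  ia <- match(common, de_a$feature)
  ib <- match(common, de_b$feature)
  sig <- !is.na(de_a$FDR[ia]) & !is.na(de_b$FDR[ib]) &
    de_a$FDR[ia] < fdr_threshold & de_b$FDR[ib] < fdr_threshold
  if (sum(sig) < 3) stop("fewer than 3 features DE in both contrasts")
  ct <- stats::cor.test(de_a$logFC[ia][sig], de_b$logFC[ib][sig])
  list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(sig))
}
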
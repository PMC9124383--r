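DE_CLASSES <- c("UP", "DOWN", "IN_BETWEEN", "NON_DE", "NONE")

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values library composition factors, computed with
#' edgeR's `calcNormFactors` (the standard implementation): per sample, a
#' weighted mean of log ratios against the reference after trimming the
#' stated fractions of extreme M and A values, exponentiated and rescaled so
#' the factors multiply to 1.
#'
#' @param counts features x samples count matrix (>= 2 samples).
#' @param ref_column reference sample column (edgeR's automatic choice when
#'   `NULL`).
#' @param trim_M,trim_A trimmed fractions of extreme log-ratios and
#'   log-abundances.
#' @return numeric vector of per-sample scaling factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, ref_column = NULL, trim_M = 0.3, trim_A = 0.05) {
  if (ncol(counts) < 2) stop("at least two samples are required")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(colSums(counts) == 0)) stop("sample with all-zero counts")
  f <- edgeR::calcNormFactors(counts, method = "TMM", refColumn = ref_column,
                              logratioTrim = trim_M, sumTrim = trim_A)
  stats::setNames(as.numeric(f), colnames(counts))
}

#' Negative-binomial GLM likelihood-ratio test
#'
#' Fits a per-feature negative-binomial GLM (log link, offset = log
#' effective library size) of a two-group contrast and tests the group
#' coefficient with a likelihood-ratio test against chi-square with one
#' degree of freedom, via edgeR's `estimateDisp`/`glmFit`/`glmLRT`. Reported
#' log2 fold changes use a prior count of 0.5 to avoid infinite values.
#'
#' @param counts features x samples count matrix.
#' @param group factor (or coercible) of two levels; the first level is the
#'   reference, log fold changes are second vs first.
#' @param factors TMM factors from [tmm_factors()] (computed when `NULL`).
#' @return tibble: feature, logFC (log2), LR, PValue.
#' @export
nb_lrt <- function(counts, group, factors = NULL) {
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("exactly two groups are required")
  if (is.null(factors)) factors <- tmm_factors(counts)
  y <- edgeR::DGEList(counts = counts, group = group)
  y$samples$norm.factors <- factors
  design <- stats::model.matrix(~group)
  y <- edgeR::estimateDisp(y, design)
  fit <- edgeR::glmFit(y, design, prior.count = 0.5)
  lrt <- edgeR::glmLRT(fit, coef = 2)
  tt <- lrt$table
  tibble::tibble(feature = rownames(counts), logFC = tt$logFC,
                 LR = tt$LR, PValue = tt$PValue)
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up FDR adjustment (monotone, capped at 1) via `stats::p.adjust`.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return adjusted FDR values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Coverage filter for testable features
#'
#' A feature is testable when its counts-per-million reach `min_cpm` in at
#' least `min_samples` libraries (inclusive thresholds); untestable features
#' are assigned the NONE class downstream.
#'
#' @param counts features x samples count matrix.
#' @param min_cpm CPM threshold.
#' @param min_samples minimum number of libraries at or above the threshold.
#' @return logical vector per feature.
#' @export
coverage_filter <- function(counts, min_cpm = 1, min_samples = 2) {
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("library sizes must be positive")
  cpm <- cpm_normalize(counts, lib)
  rowSums(cpm >= min_cpm) >= min_samples
}

#' Five-way differential expression class
#'
#' Classes follow the strict FDR thresholds: features failing the coverage
#' filter are NONE; FDR < 0.05 yields UP or DOWN by the sign of the log2
#' fold change; FDR > 0.9 yields NON_DE; everything else (including the
#' boundary values 0.05 and 0.9) is IN_BETWEEN.
#'
#' @param fdr FDR values.
#' @param log2fc log2 fold changes.
#' @param passes_filter logical from [coverage_filter()] (recycled).
#' @return character vector of classes.
#' @export
classify_de <- function(fdr, log2fc, passes_filter = TRUE) {
  passes_filter <- rep_len(passes_filter, length(fdr))
  ifelse(!passes_filter, "NONE",
  ifelse(fdr < 0.05 & log2fc > 0, "UP",
  ifelse(fdr < 0.05 & log2fc < 0, "DOWN",
  ifelse(fdr > 0.9, "NON_DE", "IN_BETWEEN"))))
}

#' Two-group differential expression with class assignment
#'
#' Full per-contrast pipeline: coverage filter, TMM normalization, NB GLM
#' likelihood-ratio test on the testable features, BH FDR and the five-way
#' class assignment. Filtered-out features are retained in the output with
#' class NONE and NA statistics.
#'
#' @param counts features x samples count matrix.
#' @param group two-level factor over the samples.
#' @param min_cpm,min_samples coverage-filter thresholds.
#' @return DE table (tibble): feature, logFC, LR, PValue, FDR, class.
#' @export
run_de <- function(counts, group, min_cpm = 1, min_samples = 2) {
  keep <- coverage_filter(counts, min_cpm, min_samples)
  out <- tibble::tibble(feature = rownames(counts), logFC = NA_real_,
                        LR = NA_real_, PValue = NA_real_, FDR = NA_real_,
                        class = "NONE")
  if (sum(keep) > 0) {
    res <- nb_lrt(counts[keep, , drop = FALSE], group)
    res$FDR <- bh_fdr(res$PValue)
    res$class <- classify_de(res$FDR, res$logFC, TRUE)
    idx <- match(res$feature, out$feature)
    out[idx, c("logFC", "LR", "PValue", "FDR", "class")] <-
      res[, c("logFC", "LR", "PValue", "FDR", "class")]
  }
  out
}
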
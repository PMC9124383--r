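#' @importFrom methods is
NULL

GENO_STATES <- c("HOM_LYC", "HOM_PEN", "HET")
SNP_SYMBOLS <- c("LYC_ONLY", "PEN_ONLY", "BOTH", "NO_COVERAGE")

#' Call a per-SNP genotype symbol from allele counts
#'
#' A SNP with fewer than `min_reads` total reads is `NO_COVERAGE`. If both
#' parental alleles are seen and the minor allele reaches `min_minor_frac`
#' of the reads the SNP is `BOTH` (heterozygous evidence); otherwise the
#' symbol of the majority allele is returned.
#'
#' @param count_lyc,count_pen non-negative read counts supporting each
#'   parental allele (vectorised).
#' @param min_reads minimum total depth to call a symbol.
#' @param min_minor_frac minimum minor-allele read fraction for `BOTH`.
#' @return character vector of symbols.
#' @export
call_snp_symbol <- function(count_lyc, count_pen, min_reads = 1L,
                            min_minor_frac = 0.1) {
  if (any(count_lyc < 0) || any(count_pen < 0)) stop("allele counts must be non-negative")
  total <- count_lyc + count_pen
  minor <- pmin(count_lyc, count_pen)
  sym <- ifelse(total < min_reads, "NO_COVERAGE",
         ifelse(count_lyc >= 1 & count_pen >= 1 & minor / total >= min_minor_frac,
                "BOTH",
         ifelse(count_lyc >= count_pen, "LYC_ONLY", "PEN_ONLY")))
  sym
}

#' Hidden Markov model parameters for genotype smoothing
#'
#' Three hidden states (HOM_LYC, HOM_PEN, HET) with initial probabilities
#' (0.45, 0.45, 0.1) and a very small inter-state transition probability
#' (1e-9), reflecting the expectation that genotype blocks span megabases.
#' Emissions over the observable symbols (LYC_ONLY, PEN_ONLY, BOTH) are
#' parameterised by a per-symbol error rate `epsilon` and a heterozygote
#' dropout `delta`: a homozygous state emits its own symbol with
#' `1 - epsilon - epsilon^2`, the heterozygous symbol with `epsilon` and the
#' opposite homozygous symbol with `epsilon^2`; the HET state emits BOTH
#' with `1 - delta` and each single-allele symbol with `delta / 2`.
#'
#' @param epsilon per-symbol error rate.
#' @param delta heterozygote dropout probability.
#' @param initial initial state distribution over (HOM_LYC, HOM_PEN, HET).
#' @param trans_p inter-state transition probability.
#' @return list of class `hmm_params` with `initial`, `transition` and
#'   `emission` (rows = states, columns = symbols).
#' @export
hmm_params <- function(epsilon = 0.01, delta = 0.10,
                       initial = c(0.45, 0.45, 0.1), trans_p = 1e-9) {
  stopifnot(epsilon > 0, epsilon < 0.5, delta > 0, delta < 1,
            trans_p > 0, trans_p < 0.5, length(initial) == 3L)
  if (abs(sum(initial) - 1) > 1e-9) stop("initial probabilities must sum to 1")
  transition <- matrix(trans_p, 3L, 3L, dimnames = list(GENO_STATES, GENO_STATES))
  diag(transition) <- 1 - 2 * trans_p
  emission <- rbind(
    HOM_LYC = c(1 - epsilon - epsilon^2, epsilon^2, epsilon),
    HOM_PEN = c(epsilon^2, 1 - epsilon - epsilon^2, epsilon),
    HET     = c(delta / 2, delta / 2, 1 - delta)
  )
  colnames(emission) <- c("LYC_ONLY", "PEN_ONLY", "BOTH")
  stopifnot(all(abs(rowSums(transition) - 1) < 1e-12),
            all(abs(rowSums(emission) - 1) < 1e-12))
  structure(list(initial = stats::setNames(initial, GENO_STATES),
                 transition = transition, emission = emission),
            class = "hmm_params")
}

#' Viterbi decoding of a SNP symbol track
#'
#' Returns the maximum a-posteriori hidden-state path for a sequence of
#' observed symbols, computed in log space. `NO_COVERAGE` symbols must be
#' removed before decoding (the genotype map interpolates across uncovered
#' spans instead). Ties are broken deterministically in the fixed state
#' order HOM_LYC < HOM_PEN < HET.
#'
#' @param symbols character vector of symbols in {LYC_ONLY, PEN_ONLY, BOTH}.
#' @param params an [hmm_params()] object.
#' @return character vector of states, same length as `symbols`.
#' @export
viterbi_genotype <- function(symbols, params = hmm_params()) {
  n <- length(symbols)
  if (n == 0L) return(character(0))
  if (any(symbols == "NO_COVERAGE")) {
    stop("remove NO_COVERAGE symbols before decoding")
  }
  obs <- match(symbols, colnames(params$emission))
  if (anyNA(obs)) stop("unknown symbol in track")
  log_e <- log(params$emission)
  log_t <- log(params$transition)
  log_i <- log(params$initial)

  delta <- matrix(NA_real_, 3L, n)
  psi <- matrix(NA_integer_, 3L, n)
  delta[, 1L] <- log_i + log_e[, obs[1L]]
  if (n > 1L) {
    for (t in 2L:n) {
      cand <- delta[, t - 1L] + log_t  # cand[i, j]: from i into j
      best <- apply(cand, 2L, which.max)  # first max -> fixed-order ties
      psi[, t] <- best
      delta[, t] <- cand[cbind(best, 1:3)] + log_e[, obs[t]]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[, n])
  if (n > 1L) {
    for (t in (n - 1L):1L) path[t] <- psi[path[t + 1L], t + 1L]
  }
  GENO_STATES[path]
}

#' Convert a per-SNP state path into genome segments
#'
#' Between adjacent SNPs assigned different states the segment boundary is
#' placed at the midpoint (0-based floor of the mean of the two 0-based
#' positions); the first and last segments extend to the chromosome ends,
#' which is how uncovered flanks and the intervals between transcribed
#' regions inherit the genotype of their neighbourhood. A chromosome with no
#' decoded SNPs yields one UNKNOWN segment.
#'
#' @param path character vector of states per SNP.
#' @param positions 1-based SNP positions aligned with `path`.
#' @param chrom_length chromosome length in bp.
#' @return tibble: start, end (0-based half-open), state; tiles
#'   `[0, chrom_length)` exactly with adjacent segments differing in state.
#' @export
segments_from_path <- function(path, positions, chrom_length) {
  if (length(path) != length(positions)) stop("path and positions must align")
  if (any(positions > chrom_length)) stop("SNP position exceeds chromosome length")
  if (length(path) == 0L) {
    return(tibble::tibble(start = 0, end = chrom_length, state = "UNKNOWN"))
  }
  o <- order(positions)
  path <- path[o]; pos0 <- positions[o] - 1
  change <- which(path[-1L] != path[-length(path)])
  cuts <- floor((pos0[change] + pos0[change + 1L]) / 2)
  bounds <- c(0, cuts, chrom_length)
  tibble::tibble(start = bounds[-length(bounds)], end = bounds[-1L],
                 state = path[c(change, length(path))])
}

#' Genome-wide genotype map from allele counts
#'
#' Runs symbol calling, drops uncovered SNPs, Viterbi-decodes each
#' chromosome and interpolates segments, producing a map that tiles the
#' genome with HOM_LYC / HOM_PEN / HET segments (UNKNOWN for chromosomes
#' without covered SNPs).
#'
#' @param counts allele-count tibble (chrom, pos, count_lyc, count_pen).
#' @param genome genome length table (chrom, length).
#' @param params an [hmm_params()].
#' @param min_reads,min_minor_frac symbol-calling thresholds, see
#'   [call_snp_symbol()].
#' @return genotype map tibble: chrom, start, end, state.
#' @export
genotype_sample <- function(counts, genome, params = hmm_params(),
                            min_reads = 1L, min_minor_frac = 0.1) {
  dplyr::bind_rows(lapply(seq_len(nrow(genome)), function(i) {
    ch <- genome$chrom[i]
    L <- genome$length[i]
    cc <- counts[counts$chrom == ch, , drop = FALSE]
    cc <- cc[order(cc$pos), , drop = FALSE]
    sym <- call_snp_symbol(cc$count_lyc, cc$count_pen, min_reads, min_minor_frac)
    keep <- sym != "NO_COVERAGE"
    seg <- segments_from_path(viterbi_genotype(sym[keep], params),
                              cc$pos[keep], L)
    seg$chrom <- ch
    seg[, c("chrom", "start", "end", "state")]
  }))
}

#' Genome fraction per genotype state
#'
#' @param map genotype map tibble (chrom, start, end, state).
#' @return named numeric vector over HOM_LYC, HOM_PEN, HET, UNKNOWN summing
#'   to 1.
#' @export
genotype_fractions <- function(map) {
  len <- map$end - map$start
  total <- sum(len)
  states <- c(GENO_STATES, "UNKNOWN")
  out <- vapply(states, function(s) sum(len[map$state == s]) / total, numeric(1))
  stopifnot(abs(sum(out) - 1) < 1e-9)
  out
}

#' Select features fully contained in segments of one genotype state
#'
#' A feature qualifies only if its whole span lies inside a single segment
#' of the requested state (the strict reading of restricting analysis to
#' homozygous transcribed regions); boundary-straddling features are
#' excluded.
#'
#' @param map genotype map tibble (chrom, start, end, state).
#' @param features tibble of intervals (chrom, start, end, plus any id
#'   columns), same 0-based half-open coordinates as the map.
#' @param state state to select for.
#' @return the subset of `features` contained in `state` segments.
#' @export
select_features_in_state <- function(map, features, state) {
  if (any(features$end < features$start)) stop("malformed feature intervals")
  seg <- map[map$state == state, , drop = FALSE]
  if (nrow(seg) == 0L || nrow(features) == 0L) return(features[0, , drop = FALSE])
  q <- GenomicRanges::GRanges(features$chrom,
                              IRanges::IRanges(features$start + 1, features$end))
  s <- GenomicRanges::GRanges(seg$chrom, IRanges::IRanges(seg$start + 1, seg$end))
  hits <- GenomicRanges::findOverlaps(q, s, type = "within")
  features[sort(unique(S4Vectors::queryHits(hits))), , drop = FALSE]
}

#' Length-weighted agreement between an inferred and a true genotype map
#'
#' @param inferred,truth genotype map tibbles tiling the same genome.
#' @return fraction of genome length on which the inferred state equals the
#'   true state.
#' @export
genotype_accuracy <- function(inferred, truth) {
  total <- 0
  agree <- 0
  for (ch in unique(truth$chrom)) {
    a <- inferred[inferred$chrom == ch, , drop = FALSE]
    b <- truth[truth$chrom == ch, , drop = FALSE]
    bounds <- sort(unique(c(a$start, a$end, b$start, b$end)))
    mids <- (bounds[-1L] + bounds[-length(bounds)]) / 2
    len <- diff(bounds)
    sa <- a$state[findInterval(mids, a$start)]
    sb <- b$state[findInterval(mids, b$start)]
    total <- total + sum(len)
    agree <- agree + sum(len[sa == sb])
  }
  agree / total
}
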
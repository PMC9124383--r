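#' Simulate parental genomes, diagnostic SNPs and transcribed regions
#'
#' Draws a biallelic parent-diagnostic SNP map (one allele fixed in
#' *S. lycopersicum*, the other in *S. pennellii*), a genome length table and
#' a set of non-overlapping transcribed regions. SNP counts per chromosome
#' are Poisson with rate `chrom_length * snp_density`; positions are uniform
#' without replacement. Transcribed regions of length `region_length` are
#' placed one per equal-width slot (uniform jitter inside the slot) so that
#' they never overlap and cover approximately `transcribed_fraction` of each
#' chromosome.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (defaults to the config seed).
#' @return a list with elements `snps` (tibble: chrom, pos 1-based, ref_lyc,
#'   alt_pen), `genome` (tibble: chrom, length) and `regions` (tibble:
#'   chrom, start, end; 0-based half-open).
#' @export
simulate_parents <- function(config, seed = config$seed) {
  validate_sim_config(config)
  set.seed(derive_seed(seed, 1L))
  L <- config$chrom_length
  chroms <- paste0("chr", seq_len(config$n_chroms))
  genome <- tibble::tibble(chrom = chroms, length = L)

  bases <- c("A", "C", "G", "T")
  snp_list <- lapply(chroms, function(ch) {
    n <- stats::rpois(1L, L * config$snp_density)
    n <- min(n, L)
    if (n == 0L) {
      return(tibble::tibble(chrom = character(), pos = integer(),
                            ref_lyc = character(), alt_pen = character()))
    }
    pos <- sort(sample.int(L, n))
    ref <- sample(bases, n, replace = TRUE)
    # alternate allele drawn from the three bases differing from the reference
    shift <- sample.int(3L, n, replace = TRUE)
    alt <- bases[(match(ref, bases) - 1L + shift) %% 4L + 1L]
    tibble::tibble(chrom = ch, pos = as.integer(pos), ref_lyc = ref, alt_pen = alt)
  })
  snps <- dplyr::bind_rows(snp_list)

  regions <- dplyr::bind_rows(lapply(chroms, function(ch) {
    frac <- config$transcribed_fraction
    if (frac <= 0) {
      return(tibble::tibble(chrom = character(), start = numeric(), end = numeric()))
    }
    if (frac >= 1) {
      return(tibble::tibble(chrom = ch, start = 0, end = L))
    }
    rl <- min(config$region_length, L)
    n_reg <- max(1L, round(L * frac / rl))
    slot <- L / n_reg
    rl <- min(rl, slot)
    jitter <- stats::runif(n_reg, 0, slot - rl)
    start <- floor((seq_len(n_reg) - 1) * slot + jitter)
    tibble::tibble(chrom = ch, start = start, end = pmin(start + rl, L))
  }))

  list(snps = snps, genome = genome, regions = regions)
}

# --- haplotype primitives ----------------------------------------------------
# A haplotype is a step function over [0, L): `breaks` are the internal
# 0-based change points (sorted), `alleles` (length(breaks) + 1) take values
# 1 = lyc, 2 = pen.

new_hap <- function(allele) list(breaks = numeric(0), alleles = allele)

hap_at <- function(hap, pos) hap$alleles[findInterval(pos, hap$breaks) + 1L]

collapse_hap <- function(breaks, alleles) {
  if (length(alleles) <= 1L) return(list(breaks = numeric(0), alleles = alleles))
  change <- alleles[-1L] != alleles[-length(alleles)]
  list(breaks = breaks[change], alleles = alleles[c(TRUE, change)])
}

# One meiotic product of the diploid (h1, h2): Poisson(lambda) crossovers at
# uniform positions, random starting haplotype, no interference.
make_gamete <- function(h1, h2, L, lambda) {
  nx <- stats::rpois(1L, lambda)
  xo <- sort(stats::runif(nx, 0, L))
  start <- sample.int(2L, 1L)
  brk <- sort(unique(c(h1$breaks, h2$breaks, xo)))
  mids <- (c(0, brk) + c(brk, L)) / 2
  src <- (start - 1L + findInterval(mids, xo)) %% 2L + 1L
  al <- ifelse(src == 1L, hap_at(h1, mids), hap_at(h2, mids))
  collapse_hap(brk, al)
}

# Diploid genotype mosaic of one chromosome from its two haplotypes.
mosaic_from_haps <- function(h1, h2, L) {
  brk <- sort(unique(c(h1$breaks, h2$breaks)))
  mids <- (c(0, brk) + c(brk, L)) / 2
  a1 <- hap_at(h1, mids)
  a2 <- hap_at(h2, mids)
  state <- ifelse(a1 == a2, ifelse(a1 == 1L, "HOM_LYC", "HOM_PEN"), "HET")
  cl <- collapse_hap(brk, state)
  bounds <- c(0, cl$breaks, L)
  tibble::tibble(start = bounds[-length(bounds)], end = bounds[-1L],
                 state = cl$alleles)
}

#' Simulate a selfing pedigree with recombination
#'
#' Founds each lineage with a fully heterozygous F1 (one lyc and one pen
#' haplotype per chromosome) and selfs it for `n_generations - 1` rounds.
#' Each selfing draws two independent gametes from the same parent, each with
#' a Poisson number of crossovers at uniform positions. The per-generation
#' genotype mosaic (HOM_LYC / HOM_PEN / HET segments tiling each chromosome)
#' is recorded as the ground truth for genotyping.
#'
#' @param config a [sim_config()].
#' @param n_generations pedigree depth (>= 1); generation 1 is the F1.
#' @param seed integer seed.
#' @return object of class `pedigree`: a list with `lineages` (each a list of
#'   generations, each holding `haplotypes` per chromosome and a `mosaic`
#'   tibble with columns chrom, start, end, state) and the `config`.
#' @export
simulate_pedigree <- function(config, n_generations = config$n_generations,
                              seed = config$seed) {
  validate_sim_config(config)
  if (n_generations < 1) stop("n_generations must be >= 1")
  set.seed(derive_seed(seed, 2L))
  L <- config$chrom_length
  chroms <- paste0("chr", seq_len(config$n_chroms))
  lam <- config$crossovers_per_meiosis

  lineages <- lapply(seq_len(config$n_lineages), function(l) {
    gens <- vector("list", n_generations)
    haps <- lapply(chroms, function(ch) list(h1 = new_hap(1L), h2 = new_hap(2L)))
    names(haps) <- chroms
    gens[[1L]] <- list(haplotypes = haps, mosaic = mosaic_table(haps, L))
    for (g in seq_len(n_generations - 1L) + 1L) {
      haps <- lapply(haps, function(hp) {
        list(h1 = make_gamete(hp$h1, hp$h2, L, lam),
             h2 = make_gamete(hp$h1, hp$h2, L, lam))
      })
      gens[[g]] <- list(haplotypes = haps, mosaic = mosaic_table(haps, L))
    }
    names(gens) <- paste0("F", seq_len(n_generations))
    gens
  })
  names(lineages) <- paste0("lineage", seq_len(config$n_lineages))
  structure(list(lineages = lineages, config = config), class = "pedigree")
}

mosaic_table <- function(haps, L) {
  dplyr::bind_rows(lapply(names(haps), function(ch) {
    m <- mosaic_from_haps(haps[[ch]]$h1, haps[[ch]]$h2, L)
    m$chrom <- ch
    m[, c("chrom", "start", "end", "state")]
  }))
}

#' Heterozygous genome fraction of a genotype mosaic
#'
#' @param mosaic tibble with columns chrom, start, end, state.
#' @return fraction of the tiled genome in state HET.
#' @export
het_fraction <- function(mosaic) {
  len <- mosaic$end - mosaic$start
  sum(len[mosaic$state == "HET"]) / sum(len)
}

#' Expected heterozygosity of a neutral selfing lineage
#'
#' A fully heterozygous F1 halves its expected heterozygous genome fraction
#' with every round of selfing, so generation g carries `0.5^(g - 1)`; the
#' F4 expectation is 12.5%.
#'
#' @param generation integer >= 1 (generation 1 is the F1).
#' @return expected heterozygous genome fraction.
#' @export
expected_heterozygosity <- function(generation) {
  if (any(generation < 1) || any(generation != round(generation))) {
    stop("generation must be an integer >= 1")
  }
  0.5^(generation - 1)
}

#' Simulate RNA-seq allele observations at diagnostic SNPs
#'
#' Forward model of the genotyping evidence: SNPs outside transcribed
#' regions receive zero depth; covered SNPs receive Poisson(`mean_depth`)
#' reads, each reporting the allele of a uniformly chosen haplotype, flipped
#' to the other parental allele with probability `miscall_rate`.
#'
#' @param mosaic genotype mosaic tibble (chrom, start, end, state).
#' @param snps SNP table (chrom, pos 1-based).
#' @param regions transcribed regions (chrom, start, end; 0-based half-open).
#' @param config a [sim_config()] supplying depth and miscall rate.
#' @param seed integer seed.
#' @return tibble: chrom, pos, count_lyc, count_pen (zero rows of depth are
#'   retained so callers can see uncovered SNPs).
#' @export
simulate_allele_observations <- function(mosaic, snps, regions, config,
                                         seed = config$seed) {
  validate_sim_config(config)
  set.seed(derive_seed(seed, 3L))
  if (nrow(snps) == 0L) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          count_lyc = integer(), count_pen = integer()))
  }
  out <- lapply(split(seq_len(nrow(snps)), snps$chrom), function(idx) {
    ch <- snps$chrom[idx[1L]]
    pos0 <- snps$pos[idx] - 1L
    reg <- regions[regions$chrom == ch, , drop = FALSE]
    covered <- rep(FALSE, length(pos0))
    if (nrow(reg) > 0) {
      o <- order(reg$start)
      rs <- reg$start[o]; re <- reg$end[o]
      j <- findInterval(pos0, rs)
      covered <- j >= 1L & pos0 < re[pmax(j, 1L)]
    }
    seg <- mosaic[mosaic$chrom == ch, , drop = FALSE]
    seg <- seg[order(seg$start), , drop = FALSE]
    si <- findInterval(pos0, seg$start)
    state <- seg$state[pmax(si, 1L)]
    p_lyc <- c(HOM_LYC = 1, HOM_PEN = 0, HET = 0.5)[state]

    n <- length(pos0)
    depth <- ifelse(covered, stats::rpois(n, config$mean_depth), 0L)
    true_lyc <- stats::rbinom(n, depth, p_lyc)
    eps <- config$miscall_rate
    count_lyc <- stats::rbinom(n, true_lyc, 1 - eps) +
      stats::rbinom(n, depth - true_lyc, eps)
    tibble::tibble(chrom = ch, pos = snps$pos[idx],
                   count_lyc = as.integer(count_lyc),
                   count_pen = as.integer(depth - count_lyc))
  })
  dplyr::bind_rows(out)[, c("chrom", "pos", "count_lyc", "count_pen")]
}

#' Pure-parent genotype mosaic
#'
#' Convenience truth mosaic for a parental line: every chromosome is one
#' homozygous segment.
#'
#' @param genome tibble (chrom, length).
#' @param state `"HOM_LYC"` or `"HOM_PEN"`.
#' @return mosaic tibble.
#' @export
parent_mosaic <- function(genome, state = c("HOM_LYC", "HOM_PEN")) {
  state <- match.arg(state)
  tibble::tibble(chrom = genome$chrom, start = 0, end = genome$length,
                 state = state)
}
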
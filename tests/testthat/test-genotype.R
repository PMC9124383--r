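# Symbol calling, Viterbi smoothing, segment interpolation and summaries.

test_that("per-SNP symbols follow the depth and minor-fraction rules", {
  expect_equal(call_snp_symbol(10, 0), "LYC_ONLY")
  expect_equal(call_snp_symbol(0, 10), "PEN_ONLY")
  expect_equal(call_snp_symbol(5, 5), "BOTH")
  expect_equal(call_snp_symbol(0, 0), "NO_COVERAGE")
  # minor fraction below threshold collapses to the majority symbol
  expect_equal(call_snp_symbol(19, 1, min_minor_frac = 0.1), "LYC_ONLY")
  expect_equal(call_snp_symbol(9, 1, min_minor_frac = 0.1), "BOTH")
  expect_equal(call_snp_symbol(c(3, 0), c(0, 2)), c("LYC_ONLY", "PEN_ONLY"))
  expect_error(call_snp_symbol(-1, 0), "non-negative")
})

test_that("hmm parameter matrices are stochastic", {
  par <- hmm_params(epsilon = 0.02, delta = 0.2)
  expect_equal(rowSums(par$transition), rep(1, 3), ignore_attr = TRUE)
  expect_equal(rowSums(par$emission), rep(1, 3), ignore_attr = TRUE)
  expect_equal(sum(par$initial), 1)
  expect_error(hmm_params(initial = c(0.5, 0.5, 0.5)), "sum to 1")
})

test_that("viterbi decodes unanimous and block-structured evidence", {
  par <- hmm_params()
  expect_equal(viterbi_genotype(rep("LYC_ONLY", 10), par), rep("HOM_LYC", 10))
  expect_equal(viterbi_genotype(character(0), par), character(0))
  path <- viterbi_genotype(c(rep("LYC_ONLY", 50), rep("PEN_ONLY", 50)), par)
  expect_equal(path, c(rep("HOM_LYC", 50), rep("HOM_PEN", 50)))
  expect_equal(sum(path[-1] != path[-100]), 1L)
  expect_error(viterbi_genotype(c("LYC_ONLY", "NO_COVERAGE"), par), "NO_COVERAGE")
})

test_that("viterbi equals exhaustive path maximisation on short random tracks", {
  symbols <- c("LYC_ONLY", "PEN_ONLY", "BOTH")
  set.seed(101)
  for (i in 1:200) {
    n <- sample(1:8, 1)
    track <- sample(symbols, n, replace = TRUE)
    par <- hmm_params(epsilon = sample(c(0.01, 0.05, 0.2), 1),
                      delta = sample(c(0.05, 0.1, 0.3), 1),
                      trans_p = sample(c(1e-9, 1e-3, 0.1), 1))
    got <- viterbi_genotype(track, par)
    oracle <- brute_force_viterbi(track, par)
    expect_equal(hmm_path_logp(got, track, par), oracle$logp, tolerance = 1e-9)
    if (oracle$unique) expect_equal(got, oracle$path)
  }
})

test_that("a single discordant symbol flanked by concordant evidence never flips the path", {
  par <- hmm_params()
  set.seed(7)
  for (i in 1:50) {
    n_flank <- sample(3:10, 1)
    base <- sample(c("LYC_ONLY", "PEN_ONLY", "BOTH"), 1)
    discord <- sample(setdiff(c("LYC_ONLY", "PEN_ONLY", "BOTH"), base), 1)
    track <- c(rep(base, n_flank), discord, rep(base, n_flank))
    path <- viterbi_genotype(track, par)
    expect_equal(length(unique(path)), 1L)
  }
})

test_that("segment interpolation places midpoint boundaries and tiles the chromosome", {
  # uniform path collapses to one full-length segment
  seg <- segments_from_path(rep("HOM_LYC", 5), c(10, 20, 30, 40, 50), 1000)
  expect_equal(nrow(seg), 1L)
  expect_equal(c(seg$start, seg$end), c(0, 1000))

  # state switch between 1-based SNPs 101 and 201 cuts at 0-based 150
  seg2 <- segments_from_path(c("HOM_LYC", "HOM_PEN"), c(101, 201), 400)
  expect_equal(seg2$end[1], 150)
  expect_equal(seg2$start[2], 150)
  expect_equal(seg2$state, c("HOM_LYC", "HOM_PEN"))

  expect_equal(segments_from_path(character(0), numeric(0), 500)$state, "UNKNOWN")
  expect_error(segments_from_path("HOM_LYC", 600, 500), "exceeds")

  # property: random paths always tile [0, L)
  set.seed(11)
  for (i in 1:25) {
    n <- sample(1:30, 1)
    pos <- sort(sample.int(999, n))
    path <- sample(c("HOM_LYC", "HOM_PEN", "HET"), n, replace = TRUE)
    s <- segments_from_path(path, pos, 1000)
    expect_equal(s$start[1], 0)
    expect_equal(s$end[nrow(s)], 1000)
    if (nrow(s) > 1) {
      expect_equal(s$start[-1], s$end[-nrow(s)])
      expect_true(all(s$state[-1] != s$state[-nrow(s)]))
    }
  }
})

test_that("genotype fractions are a probability vector over the four states", {
  one <- tibble::tibble(chrom = "chr1", start = 0, end = 100, state = "HOM_PEN")
  expect_equal(unname(genotype_fractions(one)), c(0, 1, 0, 0))
  set.seed(5)
  for (i in 1:10) {
    cuts <- sort(sample.int(999, 5))
    m <- tibble::tibble(chrom = "chr1", start = c(0, cuts), end = c(cuts, 1000),
                        state = sample(c("HOM_LYC", "HOM_PEN", "HET", "UNKNOWN"),
                                       6, replace = TRUE))
    expect_equal(sum(genotype_fractions(m)), 1)
  }
})

test_that("feature selection requires full containment in one state", {
  map <- tibble::tibble(chrom = "chr1", start = c(0, 500, 800),
                        end = c(500, 800, 1000),
                        state = c("HOM_LYC", "HET", "HOM_PEN"))
  feats <- tibble::tibble(id = c("inside", "straddle", "in_het"),
                          chrom = "chr1", start = c(100, 400, 550),
                          end = c(200, 600, 700))
  expect_equal(select_features_in_state(map, feats, "HOM_LYC")$id, "inside")
  expect_equal(select_features_in_state(map, feats, "HET")$id, "in_het")
  expect_equal(nrow(select_features_in_state(map, feats, "HOM_PEN")), 0L)
  # states are exclusive: no feature selected for two different states
  lyc <- select_features_in_state(map, feats, "HOM_LYC")$id
  pen <- select_features_in_state(map, feats, "HOM_PEN")$id
  expect_length(intersect(lyc, pen), 0L)
  bad <- tibble::tibble(chrom = "chr1", start = 10, end = 5)
  expect_error(select_features_in_state(map, bad, "HET"), "malformed")
})

test_that("expected heterozygosity follows the selfing series", {
  expect_equal(expected_heterozygosity(1), 1)
  expect_equal(expected_heterozygosity(2), 0.5)
  expect_equal(expected_heterozygosity(4), 0.125)
  expect_error(expected_heterozygosity(0), "generation")
})

test_that("the genotype map recovers a simulated F4 mosaic", {
  cfg <- sim_config(n_lineages = 1L)
  p <- simulate_parents(cfg)
  ped <- simulate_pedigree(cfg)
  truth <- ped$lineages[[1]][[cfg$n_generations]]$mosaic
  obs <- simulate_allele_observations(truth, p$snps, p$regions, cfg)
  map <- genotype_sample(obs, p$genome)
  expect_gte(genotype_accuracy(map, truth), 0.95)
})
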
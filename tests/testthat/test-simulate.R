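# Synthetic-data generator: parents, pedigree, allele observations, counts.

test_that("parent simulation produces sorted unique diagnostic SNPs at the requested density", {
  cfg <- sim_config(n_chroms = 1L, chrom_length = 1e6, snp_density = 1e-3)
  counts <- vapply(1:5, function(s) nrow(simulate_parents(cfg, seed = s)$snps),
                   numeric(1))
  # Poisson(1000): each draw within 4 SD
  expect_true(all(abs(counts - 1000) < 4 * sqrt(1000)))

  p <- simulate_parents(cfg, seed = 1)
  expect_false(is.unsorted(p$snps$pos, strictly = TRUE))
  expect_true(all(p$snps$ref_lyc != p$snps$alt_pen))

  empty <- simulate_parents(sim_config(snp_density = 0))
  expect_equal(nrow(empty$snps), 0L)
})

test_that("transcribed regions cover the configured genome fraction without overlap", {
  cfg <- sim_config(n_chroms = 2L, chrom_length = 5e5, transcribed_fraction = 0.3)
  p <- simulate_parents(cfg)
  covered <- sum(p$regions$end - p$regions$start) / sum(p$genome$length)
  expect_equal(covered, 0.3, tolerance = 0.02)
  for (ch in unique(p$regions$chrom)) {
    r <- p$regions[p$regions$chrom == ch, ]
    r <- r[order(r$start), ]
    expect_true(all(r$start[-1] >= r$end[-nrow(r)]))
  }

  full <- simulate_parents(sim_config(transcribed_fraction = 1))
  obs <- simulate_allele_observations(
    parent_mosaic(full$genome, "HOM_LYC"), full$snps, full$regions,
    sim_config(transcribed_fraction = 1, mean_depth = 30))
  # with full transcription every SNP should be coverable
  expect_gt(mean(obs$count_lyc + obs$count_pen > 0), 0.99)
})

test_that("selfing without recombination reproduces single-segment Mendelian chromosomes", {
  cfg <- sim_config(n_chroms = 4L, chrom_length = 1e5,
                    crossovers_per_meiosis = 0, n_lineages = 1L)
  states <- unlist(lapply(1:40, function(s) {
    ped <- simulate_pedigree(cfg, n_generations = 2L, seed = s)
    m <- ped$lineages[[1]]$F2$mosaic
    # each chromosome is one whole segment
    expect_equal(nrow(m), 4L)
    m$state
  }))
  frac <- table(factor(states, c("HOM_LYC", "HOM_PEN", "HET"))) / length(states)
  # 1/4, 1/4, 1/2 within binomial noise (n = 160)
  expect_equal(unname(frac["HET"]), 0.5, tolerance = 0.15)
  expect_equal(unname(frac["HOM_LYC"] + frac["HOM_PEN"]), 0.5, tolerance = 0.15)
})

test_that("pedigree mosaics tile every chromosome and heterozygosity decays as 2^-(g-1)", {
  cfg <- sim_config(n_chroms = 1L, chrom_length = 1e6, n_lineages = 1L)
  n_rep <- 400L
  hets <- matrix(NA_real_, n_rep, 3L)
  for (s in seq_len(n_rep)) {
    ped <- simulate_pedigree(cfg, n_generations = 4L, seed = s)
    for (g in 2:4) {
      m <- ped$lineages[[1]][[paste0("F", g)]]$mosaic
      expect_equal(m$start[1], 0)
      expect_equal(m$end[nrow(m)], cfg$chrom_length)
      if (nrow(m) > 1) {
        expect_equal(m$start[-1], m$end[-nrow(m)])
        expect_true(all(m$state[-1] != m$state[-nrow(m)]))
      }
      hets[s, g - 1L] <- het_fraction(m)
    }
  }
  for (g in 2:4) {
    exp_het <- expected_heterozygosity(g)
    se <- stats::sd(hets[, g - 1L]) / sqrt(n_rep)
    expect_lt(abs(mean(hets[, g - 1L]) - exp_het), 3 * se + 1e-12)
  }
})

test_that("identical seed and configuration give identical simulation output", {
  cfg <- sim_config(n_chroms = 1L, chrom_length = 2e5)
  expect_identical(simulate_parents(cfg, seed = 9), simulate_parents(cfg, seed = 9))
  p1 <- simulate_pedigree(cfg, seed = 9)
  p2 <- simulate_pedigree(cfg, seed = 9)
  expect_identical(p1$lineages, p2$lineages)
  s1 <- simulate_counts(sim_config(n_chroms = 1L, chrom_length = 1e5), seed = 9)
  s2 <- simulate_counts(sim_config(n_chroms = 1L, chrom_length = 1e5), seed = 9)
  expect_identical(s1$srna$counts, s2$srna$counts)
  expect_identical(s1$truth, s2$truth)
})

test_that("allele observations follow the stated read model", {
  cfg <- sim_config(n_chroms = 1L, chrom_length = 5e5, miscall_rate = 0,
                    transcribed_fraction = 1, mean_depth = 10)
  p <- simulate_parents(cfg)

  # homozygous sample without miscalls shows only the matching allele
  obs <- simulate_allele_observations(parent_mosaic(p$genome, "HOM_LYC"),
                                      p$snps, p$regions, cfg)
  expect_true(all(obs$count_pen == 0))
  expect_gt(sum(obs$count_lyc), 0)

  # heterozygous sample: per-SNP lyc fraction is Binomial(depth, 0.5)
  het_mosaic <- tibble::tibble(chrom = p$genome$chrom, start = 0,
                               end = p$genome$length, state = "HET")
  obs_het <- simulate_allele_observations(het_mosaic, p$snps, p$regions, cfg,
                                          seed = 3)
  covered <- obs_het$count_lyc + obs_het$count_pen > 0
  frac <- obs_het$count_lyc[covered] / (obs_het$count_lyc + obs_het$count_pen)[covered]
  expect_equal(mean(frac), 0.5, tolerance = 0.02)

  # pure-pen with miscalls: P(any lyc read at a site) = 1 - (1-eps)^depth
  cfg_e <- sim_config(n_chroms = 1L, chrom_length = 5e5, miscall_rate = 0.01,
                      transcribed_fraction = 1, mean_depth = 10)
  obs_pen <- simulate_allele_observations(parent_mosaic(p$genome, "HOM_PEN"),
                                          p$snps, p$regions, cfg_e, seed = 4)
  depth <- obs_pen$count_lyc + obs_pen$count_pen
  covered <- depth > 0
  expected <- mean(1 - 0.99^depth[covered])
  observed <- mean(obs_pen$count_lyc[covered] > 0)
  # binomial sampling error over ~1000 covered sites: allow ~3 SE
  expect_lt(abs(observed - expected), 0.03)
})

test_that("count simulation carries its truth ledger and the configured effect sizes", {
  # no DE structure: truth all non-DE and group means agree
  cfg0 <- sim_config(n_chroms = 1L, chrom_length = 2e5, frac_de_loci = 0)
  s0 <- simulate_counts(cfg0)
  expect_true(all(!s0$truth$bins$is_de))
  sheet <- s0$samples
  m_par <- rowMeans(s0$srna$totals[, sheet$sample[sheet$group == "lyc"]])
  m_hyb <- rowMeans(s0$srna$totals[, sheet$sample[sheet$group == "F4_L1"]])
  expect_equal(mean(m_hyb), mean(m_par), tolerance = 0.05)

  # log2fc_de = 2 with no spread: empirical hybrid/parent mean ratio ~ 4
  cfg2 <- sim_config(n_chroms = 1L, chrom_length = 1e6, frac_de_loci = 0.3,
                     frac_shared_de = 1, lfc_sd = 0, frac_de_up = 1,
                     nb_mean_log_range = log(c(50, 200)))
  s2 <- simulate_counts(cfg2)
  de <- s2$truth$bins$is_de
  expect_gte(sum(de), 1000)
  sheet <- s2$samples
  ratio <- mean(s2$srna$totals[de, sheet$sample[sheet$group == "F4_L1"]]) /
    mean(s2$srna$totals[de, sheet$sample[sheet$group == "lyc"]])
  expect_equal(ratio, 4, tolerance = 0.1)

  # all matrices are non-negative integers and every feature has truth
  expect_true(all(s2$srna$totals >= 0))
  expect_true(all(s2$srna$totals == round(s2$srna$totals)))
  expect_setequal(rownames(s2$srna$totals), s2$truth$bins$bin)
  expect_setequal(rownames(s2$genes$counts), s2$truth$genes$gene)

  # size-resolved counts sum to the totals
  by_bin <- tapply(s2$srna$counts$count, s2$srna$counts$bin, sum)
  tot_bin <- rowSums(s2$srna$totals)
  expect_equal(as.vector(by_bin[names(tot_bin)[tot_bin > 0]]),
               unname(tot_bin[tot_bin > 0]))
})

test_that("size mixes concentrate reads where configured", {
  mix22 <- c(`20` = 0, `21` = 0, `22` = 1, `23` = 0, `24` = 0, `25` = 0)
  cfg <- sim_config(n_chroms = 1L, chrom_length = 2e5, size_mix_DE = mix22)
  s <- simulate_counts(cfg)
  de_bins <- s$truth$bins$bin[s$truth$bins$is_de]
  cc <- s$srna$counts[s$srna$counts$bin %in% de_bins, ]
  expect_true(all(cc$size == 22))
})
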
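#' Run the full simulate-genotype-count-test-enrich pipeline
#'
#' Orchestrates every stage of the analysis on synthetic data: simulate
#' parents and selfing pedigree, genotype the F4 of each lineage (and pure
#' parental samples) from simulated RNA-seq allele observations, tile the
#' genome into 200-nt sRNA loci, simulate annotated size-resolved sRNA and
#' gene counts, run per-lineage hybrid-vs-parent and WT-vs-dcl2
#' differential expression, and compute the enrichment summaries
#' (cross-lineage overlap ratios, feature/TE-order enrichment, size
#' profiles, DCL2 cross-classification, gene-set Fisher overlap and
#' fold-change concordance). All stage outputs are written to `out_dir`
#' as plain-text artifacts and listed, with MD5 checksums, in
#' `manifest.tsv`; the run is deterministic given `seed`.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if missing).
#' @param seed global seed; fanned out to per-stage seeds by fixed
#'   derivation.
#' @return (invisibly) a list with the in-memory results of every stage:
#'   `parents`, `pedigree`, `genotype` (maps, fractions, accuracy), `sim`
#'   (the [simulate_counts()] output), `de` (per-contrast DE tables),
#'   `enrichment`, and the `manifest` tibble.
#' @export
run_pipeline <- function(config, out_dir, seed = config$seed) {
  validate_sim_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(...) cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                                    sprintf(...)), file = log_path, append = TRUE)
  cat("", file = log_path)
  write_sim_config(config, file.path(out_dir, "config.yaml"))

  # stage 1: parents ----------------------------------------------------------
  logf("stage parents: %d chrom x %g bp, snp density %g", config$n_chroms,
       config$chrom_length, config$snp_density)
  parents <- simulate_parents(config, seed = derive_seed(seed, 10L))
  write_tsv_table(parents$snps, file.path(out_dir, "snps.tsv"))
  write_tsv_table(parents$genome, file.path(out_dir, "genome.tsv"))
  regions_bed <- parents$regions
  regions_bed$state <- "transcribed"
  write_bed(regions_bed, file.path(out_dir, "transcribed_regions.bed"))

  # stage 2: pedigree ---------------------------------------------------------
  logf("stage pedigree: %d lineages, %d generations", config$n_lineages,
       config$n_generations)
  ped <- simulate_pedigree(config, seed = derive_seed(seed, 20L))
  for (ln in names(ped$lineages)) {
    f4 <- ped$lineages[[ln]][[config$n_generations]]
    write_bed(f4$mosaic, file.path(out_dir, paste0("truth_mosaic_", ln, ".bed")))
  }

  # stage 3: genotyping -------------------------------------------------------
  logf("stage genotyping")
  params <- hmm_params(epsilon = max(config$miscall_rate, 1e-3))
  geno <- list()
  frac_rows <- list()
  acc_rows <- list()
  samples_to_type <- c(
    stats::setNames(lapply(names(ped$lineages), function(ln)
      ped$lineages[[ln]][[config$n_generations]]$mosaic), names(ped$lineages)),
    list(parent_lyc = parent_mosaic(parents$genome, "HOM_LYC"),
         parent_pen = parent_mosaic(parents$genome, "HOM_PEN")))
  for (i in seq_along(samples_to_type)) {
    nm <- names(samples_to_type)[i]
    obs <- simulate_allele_observations(samples_to_type[[nm]], parents$snps,
                                        parents$regions, config,
                                        seed = derive_seed(seed, 30L + i))
    map <- genotype_sample(obs, parents$genome, params)
    geno[[nm]] <- map
    write_bed(map, file.path(out_dir, paste0("genotype_map_", nm, ".bed")))
    fr <- genotype_fractions(map)
    frac_rows[[nm]] <- tibble::tibble(sample = nm, state = names(fr), fraction = fr)
    acc_rows[[nm]] <- tibble::tibble(
      sample = nm, accuracy = genotype_accuracy(map, samples_to_type[[nm]]))
  }
  fractions <- dplyr::bind_rows(frac_rows)
  accuracy <- dplyr::bind_rows(acc_rows)
  write_tsv_table(fractions, file.path(out_dir, "genotype_fractions.tsv"))
  write_tsv_table(accuracy, file.path(out_dir, "genotype_accuracy.tsv"))

  # stage 4: bins + counts -----------------------------------------------------
  logf("stage counts: bin width %d", as.integer(config$bin_width))
  sim <- simulate_counts(config, seed = derive_seed(seed, 40L))
  bins_bed <- sim$bins
  bins_bed$state <- sim$bins$bin
  write_bed(bins_bed, file.path(out_dir, "bins.bed"))
  write_tsv_table(sim$features, file.path(out_dir, "features.tsv"))
  write_counts_tsv(sim$srna$totals, file.path(out_dir, "srna_counts.tsv"))
  write_sized_counts_tsv(sim$srna, file.path(out_dir, "srna_counts_sized.tsv"))
  write_counts_tsv(sim$genes$counts, file.path(out_dir, "gene_counts.tsv"))
  write_tsv_table(sim$samples, file.path(out_dir, "srna_samples.tsv"))

  # stage 5: differential expression -------------------------------------------
  logf("stage de")
  sheet <- sim$samples
  parent_cols <- sheet$sample[sheet$group == "lyc"]
  de <- list()
  for (l in seq_len(config$n_lineages)) {
    grp <- paste0("F4_L", l)
    cols <- c(parent_cols, sheet$sample[sheet$group == grp])
    de[[grp]] <- run_de(sim$srna$totals[, cols],
                        factor(rep(c("lyc", grp), each = length(parent_cols)),
                               levels = c("lyc", grp)))
    write_tsv_table(de[[grp]], file.path(out_dir, paste0("de_srna_", grp, ".tsv")))
  }
  wt_cols <- sheet$sample[sheet$group == "WT"]
  d2_cols <- sheet$sample[sheet$group == "dcl2"]
  de$dcl2 <- run_de(sim$srna$totals[, c(wt_cols, d2_cols)],
                    factor(rep(c("WT", "dcl2"), c(length(wt_cols), length(d2_cols))),
                           levels = c("WT", "dcl2")))
  write_tsv_table(de$dcl2, file.path(out_dir, "de_srna_dcl2.tsv"))

  gsheet <- sim$genes$samples
  de_genes <- run_de(sim$genes$counts[, gsheet$group %in% c("lyc", "F4")],
                     factor(gsheet$group[gsheet$group %in% c("lyc", "F4")],
                            levels = c("lyc", "F4")))
  de_genes_dcl2 <- run_de(sim$genes$counts[, gsheet$group %in% c("WT", "dcl2")],
                          factor(gsheet$group[gsheet$group %in% c("WT", "dcl2")],
                                 levels = c("WT", "dcl2")))
  write_tsv_table(de_genes, file.path(out_dir, "de_genes_hybrid.tsv"))
  write_tsv_table(de_genes_dcl2, file.path(out_dir, "de_genes_dcl2.tsv"))

  # stage 6: enrichment ---------------------------------------------------------
  logf("stage enrichment")
  lineage_names <- paste0("F4_L", seq_len(config$n_lineages))
  de_sets <- lapply(de[lineage_names], function(d)
    d$feature[d$class %in% c("UP", "DOWN")])
  universes <- lapply(de[lineage_names], function(d)
    d$feature[d$class != "NONE"])
  overlap <- overlap_matrix(de_sets, universes)
  write_tsv_table(overlap, file.path(out_dir, "overlap_matrix.tsv"))

  enr <- feature_enrichment(de[[lineage_names[1]]], sim$bins)
  write_tsv_table(enr, file.path(out_dir, "feature_enrichment.tsv"))

  hyb_sample <- sheet$sample[sheet$group == lineage_names[1]][1]
  d1 <- de[[lineage_names[1]]]
  de_bins <- d1$feature[d1$class %in% c("UP", "DOWN")]
  nonde_bins <- d1$feature[d1$class == "NON_DE"]
  profiles <- tibble::tibble(
    subset = rep(c("DE", "non_DE"), each = length(SIZE_CLASSES)),
    size = rep(SIZE_CLASSES, 2),
    cpm = c(size_profile(sim$srna, de_bins, hyb_sample),
            size_profile(sim$srna, nonde_bins, hyb_sample)))
  write_tsv_table(profiles, file.path(out_dir, "size_profiles.tsv"))

  xtab <- crosstab_dcl2(d1, de$dcl2, sim$srna, sim$bins, hyb_sample)
  write_tsv_table(xtab$cells, file.path(out_dir, "crosstab_dcl2.tsv"))

  both_testable <- intersect(de_genes$feature[de_genes$class != "NONE"],
                             de_genes_dcl2$feature[de_genes_dcl2$class != "NONE"])
  deg <- intersect(de_genes$feature[de_genes$class %in% c("UP", "DOWN")],
                   both_testable)
  d2g <- intersect(de_genes_dcl2$feature[de_genes_dcl2$class %in% c("UP", "DOWN")],
                   both_testable)
  fisher <- fisher_overlap(length(intersect(deg, d2g)), length(deg),
                           length(d2g), length(both_testable))
  concord <- logfc_concordance(de_genes, de_genes_dcl2)
  gene_summary <- tibble::tibble(
    statistic = c("fisher_odds_ratio", "fisher_p", "pearson_r", "pearson_p",
                  "n_deg", "n_d2g", "n_overlap", "n_universe", "n_concordant"),
    value = c(fisher$odds_ratio, fisher$p_value, concord$r, concord$p_value,
              length(deg), length(d2g), length(intersect(deg, d2g)),
              length(both_testable), concord$n))
  write_tsv_table(gene_summary, file.path(out_dir, "gene_overlap_summary.tsv"))

  # manifest --------------------------------------------------------------------
  files <- setdiff(list.files(out_dir), c("manifest.tsv", "pipeline.log"))
  manifest <- tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    bytes = file.size(file.path(out_dir, files)))
  write_tsv_table(manifest, file.path(out_dir, "manifest.tsv"))
  logf("done: %d artifacts", nrow(manifest))

  invisible(list(parents = parents, pedigree = ped,
                 genotype = list(maps = geno, fractions = fractions,
                                 accuracy = accuracy),
                 sim = sim, de = de,
                 de_genes = de_genes, de_genes_dcl2 = de_genes_dcl2,
                 enrichment = list(overlap = overlap, features = enr,
                                   profiles = profiles, crosstab = xtab,
                                   fisher = fisher, concordance = concord),
                 manifest = manifest))
}

#' Per-locus class trajectories across generations
#'
#' Tracks each differentially expressed locus across a series of
#' per-generation DE tables computed against the same parent: loci with
#' class UP or DOWN in at least one generation are retained, with their
#' class and log2 fold change in every generation.
#'
#' @param de_list named list of DE tables, one per generation, in
#'   generation order (e.g. F1..F4), all on the same feature set.
#' @return long tibble: feature, generation, class, logFC, ordered by
#'   feature then generation.
#' @export
generation_trajectories <- function(de_list) {
  feats <- lapply(de_list, function(d) sort(d$feature))
  if (length(unique(feats)) != 1L) stop("DE tables cover inconsistent feature sets")
  long <- dplyr::bind_rows(lapply(names(de_list), function(g) {
    d <- de_list[[g]]
    tibble::tibble(feature = d$feature, generation = g,
                   class = d$class, logFC = d$logFC)
  }))
  ever_de <- unique(long$feature[long$class %in% c("UP", "DOWN")])
  out <- long[long$feature %in% ever_de, , drop = FALSE]
  out$generation <- factor(out$generation, levels = names(de_list))
  dplyr::arrange(out, feature, generation)
}
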
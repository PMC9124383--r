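#' Simulation configuration
#'
#' Builds the parameter set that drives the synthetic-data generator. The
#' defaults define the reference study conditions used throughout the test
#' suite: a desk-scale diploid genome with parent-diagnostic SNPs, a selfing
#' pedigree founded by a fully heterozygous F1, RNA-seq allele observations
#' restricted to transcribed regions, and negative-binomial sRNA/gene counts
#' in which differentially expressed loci are 22-nt dominant, enriched at
#' endogenous pararetrovirus (EPRV) bins, DCL2-coupled, and partly shared
#' across independent lineages.
#'
#' @param seed integer seed used by default for every stochastic stage.
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length in bp (all chromosomes equal).
#' @param snp_density expected parent-diagnostic SNPs per bp.
#' @param transcribed_fraction fraction of the genome inside transcribed
#'   regions; only SNPs in these regions receive RNA-seq coverage.
#' @param region_length length in bp of each simulated transcribed region.
#' @param mean_depth mean per-SNP read depth (Poisson) inside transcribed
#'   regions.
#' @param miscall_rate per-read probability that the observed allele is
#'   flipped to the other parental allele.
#' @param crossovers_per_meiosis expected crossovers per chromosome per
#'   gamete (Poisson, uniform positions, no interference).
#' @param n_lineages number of independent selfing lineages.
#' @param n_generations pedigree depth; generation 1 is the F1.
#' @param reps_per_group biological replicates per sample group.
#' @param nb_mean_log_range range (natural log) of per-bin baseline sRNA
#'   means; baselines are drawn log-uniformly.
#' @param nb_dispersion negative-binomial dispersion of all counts.
#' @param frac_de_loci fraction of sRNA bins differentially expressed per
#'   lineage (and of genes in the gene contrast).
#' @param log2fc_de typical magnitude of the hybrid log2 fold change at DE
#'   sRNA loci; also the standard deviation of the centred gene effect.
#' @param lfc_sd spread added around `log2fc_de` for sRNA DE loci.
#' @param frac_de_up fraction of DE sRNA loci upregulated in the hybrid.
#' @param frac_shared_de fraction of each lineage's DE loci drawn from a
#'   response pool shared by all lineages.
#' @param dcl2_coupling_rho correlation between the hybrid and dcl2 latent
#'   effects at DE features.
#' @param frac_eprv_bins,frac_helitron_bins,frac_ltr_bins,frac_tir_bins
#'   fractions of bins annotated to each transposable-element order.
#' @param eprv_de_weight sampling weight multiplier making EPRV bins more
#'   likely to be chosen as DE loci.
#' @param size_mix_nonDE,size_mix_DE probability vectors over read sizes
#'   20--25 nt for non-DE (24-nt dominant) and DE (22-nt dominant) loci.
#' @param n_genes number of genes in the gene-level count matrices.
#' @param gene_mean_log_range range (natural log) of gene baseline means.
#' @param bin_width sRNA locus width in bp.
#'
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_length = 1e6,
                       snp_density = 2e-3,
                       transcribed_fraction = 0.3,
                       region_length = 2000,
                       mean_depth = 10,
                       miscall_rate = 0.01,
                       crossovers_per_meiosis = 1,
                       n_lineages = 3L,
                       n_generations = 4L,
                       reps_per_group = 3L,
                       nb_mean_log_range = log(c(0.2, 200)),
                       nb_dispersion = 0.1,
                       frac_de_loci = 0.05,
                       log2fc_de = 2,
                       lfc_sd = 0.75,
                       frac_de_up = 0.7,
                       frac_shared_de = 0.5,
                       dcl2_coupling_rho = 0.8,
                       frac_eprv_bins = 0.02,
                       frac_helitron_bins = 0.05,
                       frac_ltr_bins = 0.10,
                       frac_tir_bins = 0.05,
                       eprv_de_weight = 10,
                       size_mix_nonDE = c(`20` = 0.02, `21` = 0.08, `22` = 0.10,
                                          `23` = 0.10, `24` = 0.60, `25` = 0.10),
                       size_mix_DE = c(`20` = 0.03, `21` = 0.12, `22` = 0.55,
                                       `23` = 0.10, `24` = 0.15, `25` = 0.05),
                       n_genes = 2000L,
                       gene_mean_log_range = log(c(10, 1000)),
                       bin_width = 200) {
  cfg <- list(
    seed = as.integer(seed),
    n_chroms = as.integer(n_chroms),
    chrom_length = as.numeric(chrom_length),
    snp_density = snp_density,
    transcribed_fraction = transcribed_fraction,
    region_length = region_length,
    mean_depth = mean_depth,
    miscall_rate = miscall_rate,
    crossovers_per_meiosis = crossovers_per_meiosis,
    n_lineages = as.integer(n_lineages),
    n_generations = as.integer(n_generations),
    reps_per_group = as.integer(reps_per_group),
    nb_mean_log_range = nb_mean_log_range,
    nb_dispersion = nb_dispersion,
    frac_de_loci = frac_de_loci,
    log2fc_de = log2fc_de,
    lfc_sd = lfc_sd,
    frac_de_up = frac_de_up,
    frac_shared_de = frac_shared_de,
    dcl2_coupling_rho = dcl2_coupling_rho,
    frac_eprv_bins = frac_eprv_bins,
    frac_helitron_bins = frac_helitron_bins,
    frac_ltr_bins = frac_ltr_bins,
    frac_tir_bins = frac_tir_bins,
    eprv_de_weight = eprv_de_weight,
    size_mix_nonDE = size_mix_nonDE,
    size_mix_DE = size_mix_DE,
    n_genes = as.integer(n_genes),
    gene_mean_log_range = gene_mean_log_range,
    bin_width = bin_width
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' @param cfg a `sim_config` list.
#' @return `cfg`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config") || is.list(cfg))
  if (cfg$chrom_length <= 0) stop("chrom_length must be positive")
  if (cfg$n_chroms < 1) stop("n_chroms must be >= 1")
  if (cfg$mean_depth <= 0) stop("mean_depth must be positive")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (cfg$region_length <= 0) stop("region_length must be positive")
  if (cfg$bin_width <= 0) stop("bin_width must be positive")
  fracs <- c(transcribed_fraction = cfg$transcribed_fraction,
             miscall_rate = cfg$miscall_rate,
             frac_de_loci = cfg$frac_de_loci,
             frac_de_up = cfg$frac_de_up,
             frac_shared_de = cfg$frac_shared_de,
             frac_eprv_bins = cfg$frac_eprv_bins,
             frac_helitron_bins = cfg$frac_helitron_bins,
             frac_ltr_bins = cfg$frac_ltr_bins,
             frac_tir_bins = cfg$frac_tir_bins)
  bad <- fracs < 0 | fracs > 1
  if (any(bad)) {
    stop("fractions must lie in [0, 1]: ", paste(names(fracs)[bad], collapse = ", "))
  }
  te_total <- cfg$frac_eprv_bins + cfg$frac_helitron_bins +
    cfg$frac_ltr_bins + cfg$frac_tir_bins
  if (te_total > 1) stop("TE-order bin fractions sum to more than 1")
  if (abs(cfg$dcl2_coupling_rho) >= 1) stop("dcl2_coupling_rho must be in (-1, 1)")
  for (nm in c("size_mix_nonDE", "size_mix_DE")) {
    p <- cfg[[nm]]
    if (length(p) != 6L || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop(nm, " must be a length-6 probability vector over sizes 20-25 summing to 1")
    }
  }
  if (length(cfg$nb_mean_log_range) != 2L ||
      diff(cfg$nb_mean_log_range) < 0) {
    stop("nb_mean_log_range must be an increasing length-2 vector")
  }
  invisible(cfg)
}

#' Read / write a simulation configuration as YAML
#'
#' Scalar fields and the two size-mix vectors are stored as plain YAML
#' key-value entries so configurations can be versioned alongside results.
#'
#' @param path file path.
#' @return `read_sim_config` returns a `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$size_mix_nonDE <- unlist(raw$size_mix_nonDE)
  raw$size_mix_DE <- unlist(raw$size_mix_DE)
  raw$nb_mean_log_range <- unlist(raw$nb_mean_log_range)
  raw$gene_mean_log_range <- unlist(raw$gene_mean_log_range)
  do.call(sim_config, raw)
}

#' @param cfg a `sim_config`.
#' @rdname read_sim_config
#' @export
write_sim_config <- function(cfg, path) {
  validate_sim_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# Derive a stage-specific seed from a base seed; keeps values inside the
# 32-bit integer range expected by set.seed().
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1000 + stage) %% .Machine$integer.max)
}
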
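#' Simulate sRNA and gene count matrices with a known truth ledger
#'
#' Generates the count-level data the downstream analysis consumes:
#' negative-binomial sRNA counts per 200-nt bin resolved by read size
#' (20--25 nt) for a lyc parent, hybrid F4 lineages and a WT/dcl2 contrast,
#' plus gene-level count matrices for a hybrid-vs-parent and a WT-vs-dcl2
#' comparison. Differentially expressed loci are drawn preferentially from
#' EPRV-annotated bins, partially shared across lineages, 22-nt dominant
#' (non-DE loci are 24-nt dominant), and coupled to a DCL2-dependent
#' (downregulated-in-dcl2) effect; hybrid and dcl2 latent effects are drawn
#' jointly with correlation `dcl2_coupling_rho`. Per-locus size composition
#' is multinomial given the total count, so totals remain NB-distributed.
#'
#' @param config a [sim_config()].
#' @param bins optional bin table from [make_bins()]; defaults to tiling the
#'   configured genome.
#' @param seed integer seed.
#' @return a list of class `sim_counts`:
#'   \describe{
#'     \item{bins}{annotated bin table (logical flag columns per category).}
#'     \item{features}{feature intervals (chrom, start, end, category)
#'       emitted from the flags, suitable for [annotate_bins()].}
#'     \item{srna}{a [sized_counts()] over all sRNA samples.}
#'     \item{samples}{sample sheet (sample, group, lineage, role).}
#'     \item{genes}{gene count matrix (all gene samples) and its sheet.}
#'     \item{truth}{ledger: per-bin and per-gene truth labels and latent
#'       log2 fold changes, plus the per-lineage DE bin sets.}
#'   }
#' @export
simulate_counts <- function(config, bins = NULL, seed = config$seed) {
  validate_sim_config(config)
  set.seed(derive_seed(seed, 4L))
  if (is.null(bins)) {
    genome <- tibble::tibble(chrom = paste0("chr", seq_len(config$n_chroms)),
                             length = config$chrom_length)
    bins <- make_bins(genome, config$bin_width)
  }
  n <- nrow(bins)
  r <- config$reps_per_group
  n_lin <- config$n_lineages

  # --- annotation flags ------------------------------------------------------
  te_probs <- c(EPRV = config$frac_eprv_bins, helitron = config$frac_helitron_bins,
                LTR = config$frac_ltr_bins, TIR = config$frac_tir_bins)
  te <- sample(c(names(te_probs), "none"), n, replace = TRUE,
               prob = c(te_probs, 1 - sum(te_probs)))
  gene_flag <- stats::runif(n) < config$transcribed_fraction
  promoter_flag <- !gene_flag & c(gene_flag[-1L], FALSE) &
    c(bins$chrom[-1L], "") == bins$chrom
  ann <- bins
  ann$gene <- gene_flag
  ann$promoter <- promoter_flag
  for (ord in TE_ORDERS) ann[[ord]] <- te == ord

  features <- dplyr::bind_rows(lapply(FEATURE_CATEGORIES, function(cat) {
    f <- ann[ann[[cat]], c("chrom", "start", "end"), drop = FALSE]
    if (nrow(f) == 0) return(NULL)
    f$category <- cat
    f
  }))

  # --- DE truth --------------------------------------------------------------
  w <- ifelse(te == "EPRV", config$eprv_de_weight, 1)
  n_de <- round(config$frac_de_loci * n)
  n_shared <- round(config$frac_shared_de * n_de)
  shared <- if (n_shared > 0) sample.int(n, n_shared, prob = w) else integer(0)
  de_by_lineage <- lapply(seq_len(n_lin), function(l) {
    pool <- setdiff(seq_len(n), shared)
    extra <- n_de - n_shared
    priv <- if (extra > 0) sample(pool, extra, prob = w[pool]) else integer(0)
    sort(c(shared, priv))
  })
  names(de_by_lineage) <- paste0("lineage", seq_len(n_lin))
  de_union <- sort(unique(unlist(de_by_lineage)))

  lfc_h <- numeric(n)
  lfc_d <- numeric(n)
  if (length(de_union) > 0) {
    m <- length(de_union)
    rho <- config$dcl2_coupling_rho
    zh <- stats::rnorm(m)
    zd <- rho * zh + sqrt(1 - rho^2) * stats::rnorm(m)
    s <- ifelse(stats::runif(m) < config$frac_de_up, 1, -1)
    lfc_h[de_union] <- s * (config$log2fc_de + config$lfc_sd * zh)
    lfc_d[de_union] <- -(config$log2fc_de + config$lfc_sd * zd)
  }

  # --- sRNA totals -----------------------------------------------------------
  mu <- exp(stats::runif(n, config$nb_mean_log_range[1], config$nb_mean_log_range[2]))
  size_nb <- 1 / config$nb_dispersion

  samples <- character(0)
  groups <- character(0)
  lineage_of <- character(0)
  mean_cols <- list()
  add_group <- function(name, lineage, means) {
    for (k in seq_len(r)) {
      samples <<- c(samples, paste0(name, "_", k))
      groups <<- c(groups, name)
      lineage_of <<- c(lineage_of, lineage)
      mean_cols[[length(mean_cols) + 1L]] <<- means
    }
  }
  add_group("lyc", NA_character_, mu)
  for (l in seq_len(n_lin)) {
    f <- rep(1, n)
    f[de_by_lineage[[l]]] <- 2^lfc_h[de_by_lineage[[l]]]
    add_group(paste0("F4_L", l), paste0("lineage", l), mu * f)
  }
  add_group("WT", NA_character_, mu)
  fd <- rep(1, n); fd[de_union] <- 2^lfc_d[de_union]
  add_group("dcl2", NA_character_, mu * fd)

  mean_mat <- do.call(cbind, mean_cols)
  totals <- matrix(stats::rnbinom(length(mean_mat), mu = mean_mat, size = size_nb),
                   nrow = n, dimnames = list(bins$bin, samples))

  # --- multinomial size split ------------------------------------------------
  is_de_bin <- seq_len(n) %in% de_union
  mix <- rbind(config$size_mix_nonDE, config$size_mix_DE)[is_de_bin + 1L, , drop = FALSE]
  counts_long <- split_sizes(totals, mix)

  srna <- sized_counts(counts_long, totals)
  sheet <- tibble::tibble(sample = samples, group = groups,
                          lineage = lineage_of,
                          role = ifelse(groups == "lyc", "parent",
                                 ifelse(groups == "WT", "wt",
                                 ifelse(groups == "dcl2", "dcl2", "hybrid"))))

  # --- gene-level matrices ---------------------------------------------------
  ng <- config$n_genes
  mu_g <- exp(stats::runif(ng, config$gene_mean_log_range[1],
                           config$gene_mean_log_range[2]))
  n_de_g <- round(config$frac_de_loci * ng)
  de_g <- sort(sample.int(ng, n_de_g))
  g_lfc_h <- numeric(ng)
  g_lfc_d <- numeric(ng)
  if (n_de_g > 0) {
    rho <- config$dcl2_coupling_rho
    z1 <- stats::rnorm(n_de_g)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n_de_g)
    g_lfc_h[de_g] <- config$log2fc_de * z1
    g_lfc_d[de_g] <- config$log2fc_de * z2
  }
  gene_ids <- sprintf("gene%05d", seq_len(ng))
  g_samples <- c(paste0("lyc_", seq_len(r)), paste0("F4_", seq_len(r)),
                 paste0("WT_", seq_len(r)), paste0("dcl2_", seq_len(r)))
  g_groups <- rep(c("lyc", "F4", "WT", "dcl2"), each = r)
  g_means <- cbind(matrix(mu_g, ng, r),
                   matrix(mu_g * 2^g_lfc_h, ng, r),
                   matrix(mu_g, ng, r),
                   matrix(mu_g * 2^g_lfc_d, ng, r))
  gene_counts <- matrix(stats::rnbinom(length(g_means), mu = g_means, size = size_nb),
                        nrow = ng, dimnames = list(gene_ids, g_samples))

  truth_bins <- tibble::tibble(
    bin = bins$bin, baseline_mean = mu, te_order = te,
    gene = gene_flag, promoter = promoter_flag,
    is_de = is_de_bin, is_shared = seq_len(n) %in% shared,
    lfc_hybrid = lfc_h, lfc_dcl2 = lfc_d,
    size_mix = ifelse(is_de_bin, "DE", "nonDE"))
  truth_genes <- tibble::tibble(
    gene = gene_ids, baseline_mean = mu_g,
    is_de = seq_len(ng) %in% de_g,
    lfc_hybrid = g_lfc_h, lfc_dcl2 = g_lfc_d)

  structure(list(
    bins = ann, features = features, srna = srna, samples = sheet,
    genes = list(counts = gene_counts,
                 samples = tibble::tibble(sample = g_samples, group = g_groups)),
    truth = list(bins = truth_bins, genes = truth_genes,
                 de_by_lineage = lapply(de_by_lineage, function(i) bins$bin[i]))
  ), class = "sim_counts")
}

# Multinomial split of a totals matrix over the 20-25 nt size classes via
# sequential binomial thinning; `mix` is an n x 6 matrix of per-bin size
# probabilities. Returns the long-form nonzero counts.
split_sizes <- function(totals, mix) {
  n <- nrow(totals)
  S <- ncol(totals)
  rem <- totals
  remp <- rep(1, n)
  pieces <- vector("list", 6L)
  for (k in 1:6) {
    if (k < 6) {
      pk <- mix[, k] / remp
      pk <- pmin(pmax(pk, 0), 1)
      cnt <- matrix(stats::rbinom(n * S, as.vector(rem), rep(pk, S)),
                    nrow = n, dimnames = dimnames(totals))
      rem <- rem - cnt
      remp <- remp - mix[, k]
      remp[remp < 1e-12] <- 1e-12
    } else {
      cnt <- rem
    }
    nz <- which(cnt > 0, arr.ind = TRUE)
    if (nrow(nz) > 0) {
      pieces[[k]] <- tibble::tibble(
        bin = rownames(totals)[nz[, 1L]],
        sample = colnames(totals)[nz[, 2L]],
        size = SIZE_CLASSES[k],
        count = as.integer(cnt[nz]))
    }
  }
  dplyr::bind_rows(pieces)
}
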
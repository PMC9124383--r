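# Independent brute-force oracles used to validate the package's
# implementations on small inputs.

# Exhaustive maximisation over all 3^n hidden-state paths; returns the
# maximal log probability and the first maximising path in lexicographic
# order of the fixed state order (HOM_LYC < HOM_PEN < HET).
brute_force_viterbi <- function(symbols, params) {
  states <- c("HOM_LYC", "HOM_PEN", "HET")
  n <- length(symbols)
  obs <- match(symbols, colnames(params$emission))
  grid <- as.matrix(expand.grid(rep(list(1:3), n))[, n:1, drop = FALSE])
  logp <- apply(grid, 1, function(path) {
    lp <- log(params$initial[path[1]]) + log(params$emission[path[1], obs[1]])
    if (n > 1) {
      for (t in 2:n) {
        lp <- lp + log(params$transition[path[t - 1], path[t]]) +
          log(params$emission[path[t], obs[t]])
      }
    }
    lp
  })
  best <- which.max(logp)
  list(logp = logp[best], path = states[grid[best, ]],
       unique = sum(abs(logp - logp[best]) < 1e-12) == 1L)
}

hmm_path_logp <- function(path, symbols, params) {
  st <- match(path, rownames(params$emission))
  obs <- match(symbols, colnames(params$emission))
  lp <- log(params$initial[st[1]]) + log(params$emission[st[1], obs[1]])
  n <- length(path)
  if (n > 1) {
    for (t in 2:n) {
      lp <- lp + log(params$transition[st[t - 1], st[t]]) +
        log(params$emission[st[t], obs[t]])
    }
  }
  unname(lp)
}

# Definitional Benjamini-Hochberg step-up: FDR_(i) = min_{j >= i} p_(j) n / j.
brute_force_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Two-tailed Fisher p by exhaustive hypergeometric enumeration over all
# tables with the given margins (probability-mass rule).
enum_fisher_p <- function(n_overlap, n_a, n_b, n_universe) {
  k <- max(0, n_a + n_b - n_universe):min(n_a, n_b)
  pr <- stats::dhyper(k, n_a, n_universe - n_a, n_b)
  p_obs <- pr[match(n_overlap, k)]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Quadratic interval-overlap scan (>= 1 bp) used to validate annotate_bins.
brute_force_overlap_flags <- function(bins, features) {
  vapply(seq_len(nrow(bins)), function(i) {
    any(features$chrom == bins$chrom[i] &
          features$start < bins$end[i] &
          features$end > bins$start[i])
  }, logical(1))
}
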
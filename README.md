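# srnahyb

Count-level analysis of small RNA and gene expression changes in
interspecific tomato hybrids (*Solanum lycopersicum* × *S. pennellii*) and
their selfed F1–F4 progeny, where hybridization activates endogenous
pararetrovirus (EPRV) loci, perturbs DCL2-dependent 22-nt small RNAs, and
shifts gene expression toward a *dcl2*-mutant-like profile.

The package is aimed at analysts working from already-aligned,
count-level data (per-SNP allele counts, per-bin sRNA counts, gene
counts). It provides:

* **RNA-seq-based genotyping** — per-SNP allele calls smoothed with a
  3-state hidden Markov model (initial probabilities 0.45/0.45/0.1,
  inter-state transitions 10⁻⁹, Viterbi decoding), interpolated into a
  genome-wide mosaic of `HOM_LYC` / `HOM_PEN` / `HET` segments. Under
  neutral selfing the expected heterozygous fraction at generation *g* is
  0.5^(g−1) (12.5% at F4).
* **sRNA loci** — 200-nt adjacent non-overlapping bins, annotated against
  genes, promoters and TE orders (EPRV, helitron, LTR, TIR), with
  size-resolved (20–25 nt) counting of read records.
* **Differential expression** — TMM normalization and per-feature
  negative-binomial GLM likelihood-ratio tests (via edgeR), BH FDR, and
  the five-way class assignment `UP` / `DOWN` (FDR < 0.05), `IN_BETWEEN`
  (0.05 ≤ FDR ≤ 0.9), `NON_DE` (FDR > 0.9), `NONE` (coverage-filtered).
* **Enrichment statistics** — cross-lineage observed/expected overlap
  ratios, feature/TE-order enrichment of DE loci, size-class profiles,
  the hybrid × dcl2 3×3 cross-classification with per-cell EPRV read
  fractions, Fisher's exact gene-set overlap and fold-change concordance.
* **A synthetic-data generator** — parental SNP maps, recombinant selfing
  pedigrees, allele observations and NB count matrices with a complete
  truth ledger, so every stage is testable without downloads.

## Worked example

A full synthetic run — simulate, genotype, bin, test, enrich — on the
default study conditions (2 chromosomes × 1 Mb, 10,000 bins, 3 hybrid
lineages, a WT/dcl2 contrast, 2000 genes):

```r
library(srnahyb)
res <- run_pipeline(sim_config(), "demo_run")

res$genotype$accuracy
#>       sample  accuracy
#> 1   lineage1 0.9998355
#> 2   lineage2 0.9936292
#> 3   lineage3 0.9945917
#> 4 parent_lyc 1.0000000
#> 5 parent_pen 1.0000000

res$enrichment$features
#>   category n_testable pct_up pct_down up_down_ratio
#> 1   genome       9257  2.150    0.670          3.21
#> 2     gene       2707  2.327    0.591          3.94
#> 3 promoter       1878  2.343    0.692          3.38
#> 4     EPRV        197 15.736    3.046          5.17
#> 5 helitron        453  1.545    1.104          1.40
#> ...
```

The genotype maps recover the true F4 mosaics to > 99% of genome length,
and EPRV bins are strongly over-represented among differentially
expressed sRNA loci (18.8% DE vs 2.8% genome-wide) — the enrichment
pattern the analysis is designed to detect. Independent lineages share
far more DE loci than chance (`res$enrichment$overlap`, ratios ≫ 1), DE
loci peak at 22 nt while non-DE loci peak at 24 nt
(`res$enrichment$profiles`), and hybrid-upregulated loci fall
overwhelmingly in the DCL2-dependent (down in *dcl2*) class:

```r
res$enrichment$crosstab$tab
#>         dcl2
#> hybrid   UP DOWN NON_DE
#>   UP      0  104     12
#>   DOWN    0   35      5
#>   NON_DE 12  112   2888

res$enrichment$concordance
#> $r 0.806  $p_value 2.06e-10  $n 41
```

The gene-level hybrid and *dcl2* responses overlap non-randomly (Fisher's
exact p = 5.9e-57) with strongly correlated fold changes (Pearson
r = 0.81) — the *dcl2*-phenocopy signature.

Every artifact is also written to the output directory as TSV/BED with a
checksummed `manifest.tsv`; `inst/scripts/srnahyb-pipeline.R` is a thin
command-line front end over the same function.

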
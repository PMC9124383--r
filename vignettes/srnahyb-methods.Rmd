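---
title: "Methods: genotyping and small RNA locus analysis of Solanum hybrids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotyping and small RNA locus analysis of Solanum hybrids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

srnahyb analyses count-level sequencing data from interspecific
*Solanum lycopersicum* × *S. pennellii* hybrids and their selfed progeny.
This vignette documents the statistical models the package implements, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the design was open.

## 1. RNA-seq-based genotyping

Selfed hybrid genomes are mosaics of three diploid states — homozygous
*lyc*, homozygous *pen*, and heterozygous — and only transcribed regions
leave RNA-seq evidence. Genotyping proceeds in two stages.

**Symbol calling.** At every parent-diagnostic SNP the reads supporting
each parental allele are reduced to a symbol: `NO_COVERAGE` below
`min_reads` total reads (default 1); `BOTH` when both alleles are seen and
the minor allele reaches `min_minor_frac` (default 0.1) of the reads;
otherwise the majority allele's symbol. The minor-fraction guard keeps a
single miscalled read at a well-covered homozygous site from generating
spurious heterozygous evidence.

**HMM smoothing.** Because genotype blocks span megabases while individual
calls are noisy, the symbol track of each chromosome (uncovered SNPs
removed) is decoded with a 3-state hidden Markov model: initial state
probabilities (0.45, 0.45, 0.1) over (`HOM_LYC`, `HOM_PEN`, `HET`) and an
inter-state transition probability of 1e-9 per step. The tiny transition
probability is the smoothing strength: switching states costs roughly
`log(1e-9) ≈ -20.7` nats, so a run of several consecutive discordant
symbols is needed before a state change beats staying put, and isolated
miscalls never flip the path (a property the test suite asserts by
construction).

The emission model is the package's own design (the call-then-smooth
architecture leaves it open): symbol-level probabilities parameterised by a
per-symbol error rate ε (default 0.01) and a heterozygote dropout δ
(default 0.10),

| state | `LYC_ONLY` | `PEN_ONLY` | `BOTH` |
|---|---|---|---|
| `HOM_LYC` | 1 − ε − ε² | ε² | ε |
| `HOM_PEN` | ε² | 1 − ε − ε² | ε |
| `HET` | δ/2 | δ/2 | 1 − δ |

A symbol-level (rather than read-depth-aware) model mirrors the two-stage
call-then-smooth design and keeps the decoder independent of coverage
heterogeneity; both parameters are configurable. The (0.45, 0.45, 0.1)
vector is interpreted as the initial-state distribution; since the
transition matrix is almost exactly the identity, the distinction between
initial and stationary readings has no practical effect on the decoded
path. Ties in the Viterbi maximisation are broken in the fixed order
`HOM_LYC` < `HOM_PEN` < `HET`.

**Interpolation.** The decoded per-SNP path is converted into a genome
tiling: boundaries between SNPs of different states are placed at the
midpoint of their (0-based) positions, and the first/last segments extend
to the chromosome ends. This interpolation is what assigns genotypes to
sections without RNA-seq coverage; chromosomes with no covered SNP at all
become a single `UNKNOWN` segment. Internally all intervals are 0-based
half-open (BED convention); SNP tables and VCF output are 1-based.

Downstream analysis restricts features to *homozygous transcribed
regions*: a gene or bin qualifies only if its whole span lies inside one
segment of the requested state. Boundary-straddling features are excluded
— the strictest reading, which trades a little power for purity of the
parent-vs-hybrid comparison.

## 2. Selfing pedigree model

The expectation against which observed heterozygosity is compared comes
from neutral Mendelian selfing: a fully heterozygous F1 halves its expected
heterozygous fraction every generation, so F4 carries 1/8 = 12.5%. The
pedigree simulator implements exactly this neutral model — each selfing
draws two gametes from the same parent, each with a Poisson number of
crossovers (default 1 per chromosome per meiosis) at uniform positions,
with no interference and no fertility selection. Real F4 populations
deviate from 12.5% (selection on fertility is the suspected cause); the
simulator deliberately keeps the neutral model so the analytical
expectation is exact and testable. The recombination rate is exposed as a
parameter without any claim of fidelity to the real pedigree.

## 3. Small RNA loci and counting

The genome is sliced into 200-bp adjacent non-overlapping bins ("sRNA
loci"); a shorter terminal bin per chromosome is retained and flagged.
Reads shorter than 15 nt or longer than 40 nt are discarded; each
surviving read is assigned to exactly one bin by its 5′ position (bins
never double-count straddling reads, keeping counts additive), and reads
of 20–25 nt additionally populate the size-resolved profile. A bin carries
an annotation flag (gene, promoter, TE orders including EPRV and helitron)
iff it overlaps the feature by at least 1 bp — binary, not fractional, so a
bin can carry several flags. Promoters, where not annotated, are defined
as 1 kb upstream of the gene start, strand-aware. Normalization of profile
counts is plain counts-per-million against the total assigned library.

## 4. Differential expression and classes

Per contrast (each hybrid sample group against its parent; *dcl2* against
WT), counts are TMM-normalized and tested feature-by-feature with a
negative-binomial GLM likelihood-ratio test, implemented with edgeR
(`calcNormFactors`, `estimateDisp`, `glmFit`, `glmLRT`), BH-adjusted, and
assigned one of five classes:

* `NONE` — failed the coverage filter (CPM ≥ 1 in ≥ 2 libraries, inclusive);
* `UP` / `DOWN` — FDR < 0.05, by sign of the log2 fold change;
* `NON_DE` — FDR > 0.9;
* `IN_BETWEEN` — everything else, including the boundary values 0.05 and
  0.9 (the thresholds are strict inequalities).

Fold changes use a prior count of 0.5 so zero-count groups yield finite
estimates. The suite validates this stage by simulation rather than by
numeric identity with any particular dispersion-estimation flavour: type-I
error at nominal 0.05 must stay within [0.03, 0.07] on 5000 null NB
features (dispersion 0.1, 3 vs 3), and ≥ 80% of true log2FC = 2 features at
mean 100 must be classified UP/DOWN.

## 5. Enrichment statistics

**Cross-lineage overlap.** For a pair of samples the universe is the set
of bins/genes testable (class ≠ `NONE`) in both; the expected shared DE
count under independence is |A||B|/|U| and the reported statistic is
observed/expected. The definition of "expected" is the package's choice —
the independence product over the pairwise co-testable universe is the
standard reading of an observed-over-expected overlap ratio.

**Feature enrichment.** Per category (genome-wide, gene, promoter, TE
orders), the percentage of the category's testable bins classified UP and
DOWN, plus their ratio.

**DCL2 cross-classification.** Bins with class in {UP, DOWN, NON_DE} in
both the hybrid and the dcl2 contrast are cross-tabulated 3×3;
"in-between" bins are excluded because the three-group comparison is what
the size-profile analysis is defined on. Each cell reports its normalized
20–25 nt size profile and its EPRV read fraction (reads from EPRV-flagged
bins over all reads in the cell's bins).

**Gene-set overlap and concordance.** The DEG–D2G association is tested
with Fisher's exact test (two-tailed, probability-mass rule, as in
`stats::fisher.test`) on the universe of genes testable in both contrasts;
fold-change concordance is the Pearson correlation (via `stats::cor.test`)
of log2 fold changes over genes significant (FDR < 0.05) in both. Note
that conditioning on joint significance truncates small effects and can
push the measured correlation above the latent effect-correlation; the
generator's coupling parameter refers to the latent correlation.

## 6. The synthetic-data generator

Every stage is validated against data with known truth. The generator
emulates, at desk scale, the statistical structure the analysis assumes:

* biallelic parent-diagnostic SNP maps (Poisson positions), transcribed
  regions covering a configurable genome fraction;
* F1→F4 selfing pedigrees with recombination (Section 2) whose mosaics are
  the genotyping ground truth;
* allele observations at covered SNPs: depth ~ Poisson(`mean_depth`), each
  read reporting a uniformly chosen haplotype, miscalled with probability
  `miscall_rate`;
* NB sRNA counts per bin (dispersion 0.1) whose DE loci are drawn with a
  10× weight from EPRV bins, are 70% upregulated, carry a
  22-nt-dominant size mix (non-DE loci are 24-nt dominant), lose their
  sRNAs in *dcl2* (DCL2-dependence), and are 50% shared across lineages;
* gene-level counts whose hybrid and dcl2 effects are bivariate normal
  with correlation 0.8.

Per-locus size composition is multinomial given the total count, so totals
stay NB-distributed. The default study conditions are 2 chromosomes × 1 Mb
(10,000 bins), SNP density 2×10⁻³, 30% transcribed (2-kb regions), depth
Poisson(10), 1% miscalls, 3 lineages × 3 replicates, 5% DE loci with
log2FC ≈ ±(2 ± 0.75), baseline bin means log-uniform on [0.2, 200] (so a
realistic minority of bins fails the coverage filter), and 2000 genes with
means on [10, 1000]. The gene-effect spread (SD 2 on the log2 scale) was
chosen to match the several-log2-unit fold-change range such hybrids
display. Monte-Carlo checks use 10,000 pedigree replicates on a 1-chromosome
genome; the genotyping floor checks use 5 chromosomes × 5 Mb with ~50,000
SNPs over 5 seeds.

What the generator does **not** emulate: read-level artifacts (alignment,
multimapping, adapter chemistry), TE sequence evolution, linkage between
bin annotation and genomic position beyond the mosaic itself, fertility
selection in the pedigree, and library-composition biases beyond what NB
sampling induces. Passing tests therefore demonstrate that the estimators
recover the truth of this generative model — not that real libraries meet
its assumptions.

## 7. Numerical choices and degenerate inputs

* Viterbi runs in log space; ties break by fixed state order.
* Empty symbol tracks decode to an empty path; chromosomes without covered
  SNPs become `UNKNOWN` segments rather than errors.
* `segments_from_path` uses floor-of-midpoint boundaries, so maps tile the
  genome exactly whatever the SNP spacing.
* BH FDR delegates to `stats::p.adjust`; Fisher's test to
  `stats::fisher.test`; both are cross-checked in the suite against
  brute-force recomputations (step-up definition; exhaustive hypergeometric
  enumeration for margins ≤ 30).
* All stochastic entry points take an explicit seed; the pipeline fans a
  single global seed out to fixed per-stage seeds, so stages are
  independently reproducible and a full run is byte-deterministic.
* Zero-total libraries, empty bin subsets, inconsistent contingency
  margins, and single-group contrasts raise immediate errors rather than
  propagating NaNs.

## 8. Known limitations

* The genotyper assumes biallelic parent-diagnostic SNPs and diploidy;
  polyploid or multi-allelic sites are out of scope.
* Dispersion estimation follows edgeR's current defaults; classes near the
  FDR boundaries can differ from analyses run with other edgeR versions.
* The promoter rule (1 kb upstream) is a convention, not an annotation.
* Measured fold-change concordance is a selection-conditioned statistic
  (Section 5) and should not be read as an unbiased estimate of the latent
  hybrid–dcl2 coupling.
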
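---
title: "Methods: linking gamete chromatin state to embryonic gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking gamete chromatin state to embryonic gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gameteprog)
```

## The scientific question

Mature sperm and their immediate precursors, round spermatids, carry the
same genome but different chromatin: during spermiogenesis many promoters
lose H3K4me2/3 while retaining H3K27me3, nucleosome occupancy and DNA
methylation rise around transcription start sites (TSSs), and a small set
of developmentally important promoters ends up "programmed" — Polycomb-
repressed in sperm, but bivalent (H3K4me2/3 together with H3K27me3) in
spermatids. When haploid embryos are derived from the two cell types by
intracytoplasmic injection, genes in that programmed set become
misregulated (mostly up-regulated) in spermatid-derived embryos.

`gameteprog` implements the full quantitative pipeline needed to test this
model: TSS-anchored quantification of gamete epigenome tracks, paired
count-based differential expression with a cross-replicate consistency
filter, partial-correlation network inference over epigenetic features and
embryo expression, gene-set statistics, and DNA-fiber replication-extent
statistics. A seeded synthetic-data generator implements the programming
model itself, so every stage is testable end-to-end without external data.

## TSS-anchored signal quantification

All coordinates are 0-based, half-open (BED convention); GTF input is
converted on read. For a `+` strand gene the TSS is the feature start, for
a `-` strand gene the last base (`end - 1`). Chromosome names are matched
exactly, and genes on chromosomes absent from a track are dropped with a
logged count — silent aliasing hides errors.

Three quantifications share the promoter window `[tss - flank, tss +
flank)`, clipped at the chromosome start (clipped windows keep their
reduced width; per-base means keep them unbiased):

* **Metagene profiles** (`metagene_profile()`): per-gene windows are cut
  into equal bins (defaults: flank 2000 bp, bin 50 bp), minus-strand
  windows are flipped so upstream is always left, each bin carries the
  mean per-base signal, and bins are averaged without weighting across
  genes. Tracks are depth-scaled to signal-per-million by default. The
  profile is linear in the track, which the tests exploit.
* **Promoter levels** (`promoter_levels()`): the "overall level" of a mark
  at a promoter is
  `log2((ip_spm + c) / (input_spm + c))`, where `*_spm` are window sums
  scaled by `1e6 / total_signal` and `c` is a pseudocount (default 1
  signal-per-million unit). The pseudocount keeps every level finite and
  makes the statistic antisymmetric under swapping IP and input.
* **Promoter peaks** (`call_promoter_peaks()`): window signal is
  integerised after depth-matching the input to the IP total; the p-value
  is the upper-tail Poisson probability `P(X >= k_ip)` at rate
  `max(k_input_scaled, 1)`. The floor of one expected count guards
  promoters with empty input windows. q-values are Benjamini–Hochberg
  over all genes of one (mark, cell) pair, with peaks at `q < 0.05`. This
  is a deliberately simple, fully specified promoter-window test — the
  package's own definition, adequate for promoter-level presence calls;
  it is not a genome-wide peak caller.

## Paired differential expression

Embryo RNA-seq arrives as a genes-by-samples integer matrix with a paired
design: each of `E` experiments (default 7) contributes one sperm-derived
and one spermatid-derived embryo sample. The pipeline (`run_de()`) is:

1. **Expressed filter**: counts-per-million above 1 in at least 2 samples
   (configurable).
2. **Normalisation**: median-of-ratios size factors, rescaled to
   geometric mean 1. If no gene is positive in every sample a
   pseudocounted reference is available behind an explicit flag.
3. **Dispersion**: method-of-moments,
   `phi = max(0, (s2 - m) / m^2)` from the pooled within-group variance
   of normalised counts; by default the median across genes is used as a
   common dispersion. The median is robust to the heavy right tail of
   per-gene moment estimates at small sample sizes.
4. **Test**: a negative-binomial conditional exact test. Normalised
   counts are rounded and summed per group; conditioning on the total
   `S`, each split `s` has weight
   `NB(s; mu_a, phi/n_a) * NB(S - s; mu_b, phi/n_b)` with null means
   proportional to group size, and the two-sided p sums all splits no
   more probable than the observed one (ties included once). At
   `phi = 0` this is exactly the conditional binomial test, which is the
   oracle the tests check against. A gene with `S = 0` gets `p = 1` by
   convention.
5. **FDR**: Benjamini–Hochberg across tested genes.
6. **Consistency filter**: per-experiment fold-changes
   `log2((y_td + 0.5) / (y_sperm + 0.5))` on normalised counts; a gene is
   consistent when at least `E - 1` experiments (six of seven in the
   default design) share the sign, zeros counting toward neither side.
   The pseudocount of 0.5 keeps the per-pair fold-changes finite and
   sign-stable.

The **misregulated** set is `FDR < 0.05` plus consistency; the
**extended** set relaxes to `FDR <= 0.4` with `|logFC| >= 0.2` and no
consistency requirement, mirroring the relaxed selection used for
higher-powered network analyses.

## Partial-correlation networks

`build_feature_matrix()` joins per-gene feature tables (four histone-mark
levels, nucleosome occupancy, DNA methylation, and the mean
`log2(cpm + 0.5)` of the matching embryo group) over a selected gene set,
dropping genes missing any feature (count logged) and z-scoring every
column — marks and expression live on incomparable scales.

`partial_correlation()` shrinks the sample correlation matrix toward the
identity, `S* = (1 - lambda) R + lambda I`, inverts it and standardises
the negative precision matrix. `lambda = "auto"` uses the closed-form
optimal intensity (the ratio of summed estimated variances of the
off-diagonal correlations to their summed squares, clamped to `[0, 1]`);
`lambda = 0` recovers the classical estimate and is what the
residual-regression oracle tests use. With ~100–300 genes and 7 features
the automatic intensity is small but stabilises inversion when gene sets
are small or features nearly collinear.

Edges are tested analytically:
`t = pcor * sqrt((n - k) / (1 - pcor^2))` on `n - k` degrees of freedom,
two-sided, BH-adjusted over the `k(k-1)/2` edges; an edge is kept at
`q < 0.05`. A seeded column-rotation permutation test
(`edge_permutation_test()`) is provided as a cross-check, not the
default. Because BH controls the *false discovery rate* of the kept edge
set rather than the probability of any false edge, occasional single
false-positive edges are expected even at large `n`: with 15 true null
edges among 21, the chance that some null edge survives BH at `q < 0.05`
is in the 10–20% range. Exact recovery of a sparse planted graph in
essentially every replicate would require family-wise control, which this
package deliberately does not substitute for the stated BH rule.

## Set statistics and fibers

Enrichment uses the Pearson chi-squared test on 2x2 tables without
continuity correction (a flag enables the Yates variant); equal
proportions define `chi2 = 0`, `p = 1`, direction `none` — this takes
precedence over degenerate-table detection, so a term covering the whole
universe is simply uninformative. Set overlaps get upper-tail
hypergeometric probabilities; term enrichment runs one table per term
with BH across terms; ortholog projection collapses duplicate targets and
counts unmapped genes. Two-sample comparisons use the Kolmogorov–Smirnov
statistic with the asymptotic p-value — appropriate for the fiber samples
of 125+ observations this is designed for; small-sample exactness is
covered by a brute-force ECDF oracle in the tests, not by the API.

DNA combing fibers live on per-fiber kb axes (BED6 with the fiber id in
the chrom column; `name` is `total` or `replicated`). The replication
extent is the merged replicated length over the total length, invariant
to splitting intervals.

## The synthetic-data generator

`sim_config()` fixes the study conditions; all randomness flows from one
integer seed through one child stream per generator, so every output is
byte-reproducible and adding draws to one stage never perturbs another.

Genes (default 5000, one 25-Mb chromosome, TSSs every 5 kb, alternating
strand) fall into four classes: **programmed** (probability 0.01;
H3K27me3 in both cells, H3K4me2/3 gained in the spermatid, true
`logFC = +1.5` in spermatid-derived embryos), and the remainder split
50/25/25 into **active** (H3K4me2/3 in both cells), **repressed**
(H3K27me3 and H3K9me3 in both) and **unmarked**. A config flag can send a
fraction of programmed genes down instead of up.

Tracks are generated at 50-bp resolution: each marked promoter receives a
Gaussian bump (sd 300 bp, height 10 signal units at the mode) scaled by a
per-(gene, mark) lognormal intensity and a small per-track jitter;
occupancy and methylation bump at every TSS with sperm amplitude 1.5x the
spermatid one; inputs are flat at 1; truncated-normal background noise
(sd 0.25) is added everywhere. At programmed promoters one lognormal
*bivalency factor* multiplies the H3K4me2, H3K4me3 and H3K27me3
intensities jointly — coexisting marks covary across promoters, which is
the quantitative content of the bivalent-programming model and what makes
the spermatid H3K4–H3K27 network edge emerge.

Embryo counts are negative binomial (dispersion 0.05, Poisson limit at 0)
around means built from a lognormal baseline (meanlog 4, sdlog 1.5)
multiplied by a promoter-state factor: an active K4 state adds +0.5 log2
plus 1 log2 per natural-log unit of each K4 mark's intensity; each
repressive mark subtracts 2 log2 plus 0.3 per log-intensity unit;
methylation and occupancy subtract 0.5 per log-intensity unit. Sperm-
embryo means are scaled to the library size (default 1e6);
spermatid-embryo means are exactly `2^true_logfc` times the sperm-embryo
means, so non-programmed genes are exact nulls for the paired test. The
coupling scales were chosen once, when the generator was designed, to
give the analysis stages realistic signal-to-noise (mark levels spanning
roughly two orders of magnitude, expression responses of a fraction of
the baseline spread); they are test-bed settings, not estimates of the
biology.

What the generator deliberately does **not** emulate: read-level
sampling, fragment-length and GC structure, chromosome-scale coverage
waves, mappability artefacts, annotation errors, correlated library-
preparation effects between paired samples, and inter-gene signal
spill-over. Passing tests therefore demonstrate that the statistical
machinery behaves as specified under the programming model, not that the
pipeline is robust to every artefact of real sequencing data.

## Problem sizes and study-scale runs

Benchmarks use three scales, chosen to keep the full suite in the minutes
range on one CPU: the default 5000-gene study (about 200 expected counts
per gene) for misregulated-gene recovery and null calibration, averaged
over five seeded replicates; 1000 x 7 Gaussian samples, 50 replicates,
for planted-network recovery; and one 18,340-gene study — the expressed-
gene count scale of the motivating experiments, with the library scaled
to keep depth per gene constant — for the qualitative network-sign
analysis, where the sperm network is read on the extended set (the
higher-powered relaxed selection) and the H3K4–H3K27 bivalency edge on
the misregulated set itself. Within the misregulated set the sperm
network cannot show an expression–H3K4 edge by construction (programmed
promoters carry no sperm K4 signal), which is why the extended set is the
right substrate for that comparison.

## Numerical choices and degenerate inputs

* Ties in the conditional exact test include the observed split once,
  with a `1 + 1e-12` relative guard against floating-point ties.
* Peak scores written to BED are `-10 log10(q)` capped at 1000.
* `bh_adjust()` validates `p` in `[0, 1]`; the implementation delegates
  to the standard step-up procedure and is frozen against an enumeration
  oracle.
* Windows clipped at position 0 keep reduced width; zero-width bins drop
  out of metagene averages rather than contributing zeros.
* Constant feature columns abort network assembly with the feature name;
  a singular correlation matrix at `lambda = 0` suggests shrinkage
  instead of silently regularising.
* Empty tracks (total signal 0) are an error wherever depth scaling is
  required.
* `|pcor| = 1` yields `p = 0` with a warning rather than `NaN`.

## Limitations

The peak caller and the exact test are intentionally minimal: no
replicate-aware peak reconciliation, no empirical-Bayes dispersion
shrinkage, no GLM covariates, no TMM normalisation. The KS p-value is
asymptotic only. The network stage estimates a single Gaussian partial-
correlation structure; it is not a sparse model selector and makes no
causal claims. The pipeline treats annotation as opaque user input — one
row per gene id, first occurrence winning — and performs no ortholog
inference beyond a user-supplied map.
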
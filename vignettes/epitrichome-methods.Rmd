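---
title: "Methods: multi-tissue histone-mark integration with epitrichome"
author: "epitrichome authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-tissue histone-mark integration with epitrichome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epitrichome)
```

## Scope and problem

Glandular trichomes are the secretory organs in which *Cannabis sativa*
synthesizes cannabinoids and terpenoids, and tissue-specific chromatin is a
candidate layer of the regulation of those pathways. `epitrichome`
implements the downstream, desk-scale half of a multi-tissue histone-mark
study: it consumes per-tissue, per-replicate peak calls for two activating
marks (H3K4me3, H3K56ac), one repressive mark (H3K27me3) and the histone
variant H2A.Z, together with gene models, TPM expression tables and a
genome sequence, and produces consolidated high-confidence peak sets,
tissue-specific and bivalent chromatin, differential-expression summaries,
ontology and gene-set enrichment, motif enrichment in tissue-specific
H3K56ac loci, and distal enhancer → target-gene predictions. Read
processing, alignment and de-novo peak calling are out of scope: the
pipeline starts at peak calls and binned coverage, which is also where its
synthetic-data generator emits its outputs.

All genomic coordinates are 0-based half-open internally (the BED
convention); GFF3/GTF input is converted at the boundary. The TSS of a
minus-strand gene is `end - 1`, the last covered base, so a TSS always lies
inside its half-open gene span.

## Replicate consolidation

Two consolidation routes mirror standard practice for the two peak shapes.

**Narrow and mixed marks (H3K4me3, H3K56ac)** are consolidated with the
irreproducible discovery rate (IDR). Replicate peaks are first matched
one-to-one: all overlapping pairs are candidates, taken greedily by
descending overlap length with deterministic ties (chromosome, then start).
Unmatched singletons are discarded before fitting — a peak seen in only one
replicate carries no rank-concordance information.

The IDR model is a two-component Gaussian copula mixture. Scores (−log10 p
by default, signal value as fallback) are converted to average ranks, then
to uniform pseudo-values $u_i = (r_i - 0.5)/n$, then to pseudo-data
$z_i = G^{-1}(u_i)$ under the mixture marginal

$$G(z) = \pi_1\,\Phi\!\left(\frac{z-\mu}{\sigma}\right) + (1-\pi_1)\,\Phi(z),$$

where the reproducible component has weight $\pi_1$, mean $\mu > 0$,
standard deviation $\sigma$ and between-replicate correlation $\rho$, and
the irreproducible component is independent standard normal. Estimation is
the two-level scheme of the reference method: an inner EM (E-step: the
posterior that a pair is reproducible; CM-step: posterior-weighted moment
updates of $\pi_1, \mu, \sigma, \rho$) runs to convergence on fixed
pseudo-data, then the pseudo-data are recomputed under the updated
marginal, and the outer loop stops when no parameter moves by more than
`tol` (default 1e-4, at most 200 pseudo-data updates). A strict 1:1
interleave of pseudo-data updates and single EM cycles stalls far from the
optimum when almost every pair is reproducible, which is exactly the regime
of good replicate data; the two-level scheme does not.

Numerical choices worth knowing:

* parameters are clamped to the interior of their domains (1e-4 bounds);
* rank ties use average ranks, with no random jitter, so fits are
  deterministic;
* the inner EM also stops when the posteriors move by less than 1e-6 —
  when the reproducible component absorbs essentially all pairs, the
  vestigial null component lets $\sigma$ drift indefinitely although the
  classification is already fixed;
* if the fitted $\rho$ collapses to ≤ 0.05 the two components are not
  identifiable from the rank dependence (this is what happens on truly
  independent replicates); the fit is flagged `degenerate` and every pair
  is reported irreproducible rather than letting $\pi_1 \to 1$ declare
  everything reproducible.

The local IDR of a pair is its posterior irreproducibility; the global IDR
is the running mean of sorted local IDRs, an FDR-like quantity.
Consolidation keeps pairs with global IDR at or below the threshold — 0.05
for true narrow peaks (H3K4me3) and a deliberately less stringent 0.10 for
the mixed peak type (H3K56ac) — and reports the union span of the matched
pair with the mean replicate score; the global IDR is stored
−log10-transformed in the q-value column of the written peak files.

**Broad marks (H3K27me3, H2A.Z)** are consolidated by reciprocal-overlap
intersection: a replicate-1 domain is kept when some replicate-2 domain
covers at least 30% of *both* domains (`-f 0.3 -r` semantics). The whole
replicate-1 domain is reported; the selected pair set is symmetric in the
replicate roles even though the reported spans follow replicate 1.
Coverage tracks can be depth-matched beforehand with `scale_track()`,
which rescales base-weighted signal mass to a reference total.

## Interval algebra

The interval engine is authored in base R and validated against independent
per-base bitmap and all-pairs oracles in the test suite. Key contracts:

* `subtract_exclusive()` uses whole-interval semantics: any overlap
  disqualifies (the `-v` operation used for tissue-specific chromatin);
  `tissue_specific()` applies it sequentially against every other tissue.
* `nearest_tss()` anchors peaks at their midpoint (integer floor), the
  convention of distal-peak callers; an edge anchor (distance 0 for an
  internal TSS) is available as an alternative. Ties break to the
  lexicographically smallest gene id for determinism.
* `distal_filter()` keeps peaks strictly farther than 1,500 bp (default)
  from the nearest TSS; peaks on gene-free chromosomes are retained and
  flagged rather than silently dropped.
* `feature_distribution()` classifies each peak midpoint with priority
  promoter > TTS flank > gene body > intergenic. The windows — promoter
  TSS−1000..TSS+100, TTS flank TES..TES+100, both strand-aware — are
  package defaults; the source study never published its windows, so these
  follow common annotation-tool defaults.
* `colocalization_fisher()` merges both peak sets, counts overlapping and
  non-overlapping merged intervals, and estimates the "neither" cell as
  `genome_size / mean interval length` minus the other cells, the estimate
  used by genome-interval Fisher tools. That cell is a modelling
  convention, not data; the test suite therefore validates the *direction*
  of the statistic (p monotone non-increasing in planted overlap), never a
  particular p-value. `fisher_exact_2x2()` itself is exact (two-sided,
  conditional on margins) and is checked against full enumeration to
  1e-12.

## Expression statistics

Genes are partitioned into transcribed/untranscribed at mean TPM ≥ 1
across a tissue's replicates. Differential expression between tissues uses
a deliberately simple, documented stand-in for a count-model DE stage:
log2 fold change is the difference of mean `log2(TPM+1)` and the p-value
comes from Welch's t-test on the same scale, BH-adjusted across genes.
Genes with zero variance in both groups get p = 1. The stand-in is used
consistently everywhere, including the acceptance pipeline; negative
binomial dispersion modelling is explicitly out of scope. The
tissue-specific gene set requires log2FC > 2 (strict) and BH p.adj < 0.05
in *both* contrasts (focal vs each other tissue).

Over-representation uses the upper hypergeometric tail including the
observed overlap, BH-adjusted across terms. Preranked GSEA uses the
weighted Kolmogorov–Smirnov running sum (hit increments
$|s|^{w}$ normalized by the in-set total with $w=1$; miss decrements
$1/(N-N_{hits})$), a gene-label permutation null with a fixed seed, NES
normalized by the mean magnitude of same-sign null scores, and a
+1-smoothed permutation p. Gene-label (not phenotype) permutation is the
only option because the interface consumes a ranked list, not per-sample
phenotypes. Note that BH adjustment is *not* idempotent in general — the
suite checks it against the definitional step-up oracle and for
monotonicity in the input order statistics instead.

## Integration and enhancer–target prediction

A mark is assigned to a gene when any consolidated peak of that mark
overlaps the gene span extended 1,000 bp upstream (strand-aware); bivalent
genes carry both H3K4me3 and H3K27me3. Enhancer–target prediction runs in
a fixed order: (1) tissue-specific H3K56ac loci are filtered to midpoints
strictly more than 1,500 bp from *any* TSS; (2) each surviving locus is
matched to its nearest gene among **all** annotated genes; (3) the pair is
kept only when that gene passed the both-contrast DE filter. The ordering
matters: restricting the nearest-gene search to DE genes would attach loci
to distant DE genes even when a non-specific gene is closer, which is a
different (and more permissive) prediction; rejected loci are reported
with reasons so the difference stays auditable. Intragenic loci are
flagged, never excluded.

## Motif enrichment

Tissue-specific distal H3K56ac sequences (primary) are compared against
all focal-tissue H3K56ac sequences (control), the control choice of the
source protocol. PFMs become log-odds PWMs with a total pseudocount of
0.25 distributed by the background (uniform by default). A window matches
when its log-odds score on either strand reaches 0.8 of the motif's
maximum score — a fixed-fraction threshold, simpler and deterministic
compared with the optimized multi-threshold search of SEA-style tools, and
documented as a departure from them. Enrichment counts *sequences* with at
least one hit (never windows), uses a one-sided Fisher test in the
enrichment direction, and BH-adjusts across motifs (significance at
q < 0.05). Ambiguous bases contribute the background-weighted mean column
score.

## The synthetic study generator

`simulate_study()` emits the downstream products of a miniature
three-tissue study with planted, machine-readable ground truth. Defaults
(the reference conditions): 3 chromosomes × 1 Mb at GC 0.42; 300 genes
with log-normal lengths (median 3 kb, min 500 bp) and intergenic gaps of
at least 1 kb; 2 ChIP replicates and 3 RNA replicates; baseline TPM
log-normal with median 8 and a 20% untranscribed fraction (< 1 TPM);
40 DE genes drawn from the untranscribed pool and induced in trichome with
log2FC ~ U(2.5, 8); 15 bivalent trichome genes; 25 trichome-only distal
H3K56ac enhancer loci placed 2–50 kb from their paired DE gene's TSS with
that gene guaranteed nearest; replicate boundary jitter sd 50 bp; spurious
peaks at 0.2 of the true count per replicate with independent low scores;
true-peak replicate scores bivariate log-normal with correlation 0.8; the
planted motif consensus inserted into 60% of enhancer loci (plus an
unplanted decoy motif).

Design choices that make the planted structure exactly recoverable at zero
noise (a required property — with jitter and spurious rate both 0 the full
pipeline inverts the generator for every entity kind):

* peak and domain templates are placed so that no planted peak can bleed
  into a neighbouring gene's assignment window: adjacencies involving a
  domain-carrying gene are widened (the 1 kb minimum gap always holds; the
  gap *distribution* is exponential on top of per-adjacency minima), and
  TSS-peak widths are capped by clearance to neighbours;
* the planted trichome effect is applied on the log2(TPM+1) scale
  (trichome TPM = (base+1)·2^L − 1), so the planted L is exactly the
  quantity the stand-in DE test estimates;
* enhancer placement verifies the nearest-gene guarantee with a 400 bp
  margin after all genes are placed and re-draws violating positions
  (bounded retries, then an error before anything is written);
* one RNG stream per output kind is derived from the master seed, so
  adding an output kind does not perturb the others; identical seeds give
  byte-identical bundles.

What the generator does **not** emulate: read-level noise and mappability,
peak-width/score dependence on local chromatin, non-uniform gene density,
isoform structure, batch effects in expression, and motif occurrences in
background sequence beyond what a random genome produces. Passing the
planted-recovery tests therefore demonstrates the *correctness of the
joins and statistics*, not expected performance on real tissue data. The
generator also emits a synthetic GO-like term map (one term enriched in
the planted DE genes plus random terms) because the ontology stages
consume a term map as input; it is labelled synthetic throughout.

`truth_eval()` scores predictions against the manifest: peaks match at
≥ 0.5 reciprocal overlap within the same mark, enhancer pairs need the
same target gene plus locus overlap, genes and motifs match by id. Empty
predictions report precision 0 with a degenerate flag rather than NaN.

## Pipeline stages, determinism and problem sizes

`run_config()` holds every threshold (IDR 0.05/0.10, broad fraction 0.3,
TPM 1, log2FC 2, alpha 0.05, distal 1,500 bp, motif q 0.05) so the
reference values are the shipped defaults; `run_stage()` validates the
explicit dependency graph up front and errors before computing when an
upstream stage is missing or a threshold is out of range. Each stage
writes its outputs plus a timestamp-free key=value log (package version,
seed, input checksums, summary counts), so deterministic stages are
byte-identical on re-run. Signal-track stages (correlation at 10 kb bins,
metagene with 2 kb flanks, 40+60+40 bins) operate on binned coverage; the
source study correlated alignment files, and binned coverage is the
equivalent desk-scale object. Bin widths for generation (200 bp) and
correlation (10 kb) are package defaults; the study never stated its
choices.

The shipped problem sizes — the default generator above, 5,000 matched
pairs for IDR recovery simulations, 1,000 permutations for GSEA, 20 seeds
for calibration loops — keep the entire validation suite in the
single-digit-minutes range on one CPU while leaving each statistic enough
resolution for its stated tolerance.

## Known limitations

* The IDR fit assumes exchangeable replicates and a single reproducible
  component; multimodal score distributions can converge to a conservative
  split that classifies the lowest-ranked concordant pairs as
  irreproducible. This mirrors the reference tool's behaviour and is the
  main source of imperfect (≈0.95–0.99) tissue-specific F1 on noisy
  synthetic data.
* The co-localization "neither" cell is an estimate; treat those p-values
  as ordering devices, not calibrated probabilities.
* Motif scanning uses a 0-order background and a fixed score threshold;
  GC-biased backgrounds should be passed explicitly via the `background`
  argument.
* The nearest-gene step assigns a single target per locus; multi-gene
  enhancers and chromatin-loop validation are out of scope.
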
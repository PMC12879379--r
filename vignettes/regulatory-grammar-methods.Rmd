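---
title: "Methods: from cell-type-specific genes to synthetic regulatory grammar"
author: "regulogic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from cell-type-specific genes to synthetic regulatory grammar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulogic)
```

regulogic implements a gene-centric pipeline for dissecting the sequence
logic of cell-type-specific transcription: rank genes by how specifically
they are expressed in a target cell population, collect the regulatory
regions those genes use, search the regions for known and novel DNA motifs,
test motifs and motif pairs for enrichment, and finally design and score a
combinatorial synthetic-enhancer (STARR-seq) library that probes
orientation, copy number, position, pair and order effects directly. This
vignette explains each model, the tunable parameters, the numerical
choices, and what the synthetic-data generators do and do not emulate.

## Gene specificity ranking

Input is an already-normalized expression matrix (genes x samples) plus a
sample-to-group map (`target` vs `background`). Per gene we sum expression
over each group (`aggregate_expression()`), drop genes whose target-group
aggregate is below the cohort median (`median_filter()`; genes exactly at
the median are kept), and rank the survivors from high to low in the
target group and from low to high in the background group, with average
ranks on ties (`specificity_scores()`). The sum of the two ranks is the
specificity score in the operative sense: for a gene expressed
indiscriminately the two ranks are strongly anticorrelated (high
expression means a good target rank and a bad background rank), so the
null rank-sum distribution concentrates tightly around n + 1, while a
genuinely target-specific gene achieves two small ranks at once and falls
far into the left tail.

`partition_gene_sets()` thresholds that rank-sum distribution at
`mu - k_top * sigma` (default `k_top = 4`; strictly below = top-ranked
set) and `mu - k_comp * sigma` (default 3; strictly above = comparator
set), with the genes in between excluded from both sets, and a
bottom-ranked control set size-matched to the top set. `mu` and `sigma`
are the mean and population SD of the retained genes' rank sums. A note on
why the rank sum, and not its re-rank, must be thresholded: a re-ranked
score is uniform on 1..n, whose minimum z-score is -sqrt(3); no
observation of a uniform rank vector can sit 4 SDs below its mean, so
thresholding the re-rank would return an empty top set for every possible
input. The re-rank (`specificity_score`) is still computed and used as the
canonical ordering.

## Regulatory-region curation and gene linking

Regions are BED-convention intervals (0-based, half-open) annotated per
sample. `require_group_support()` keeps a region only if the identical
annotation occurs in at least one sample of every required group (an
overlap-based mode is available for sources that do not share annotations
across samples), and drops sex/mitochondrial chromosomes.
`merge_overlapping()` collapses regions that share at least one base;
bookended regions share none under the half-open convention and stay
separate. `classify_proximal_distal()` calls a region proximal when its
nearest edge is within 500 bp (inclusive) of any transcription start
site — edge-to-point, not midpoint-to-point, so a large region touching a
promoter is proximal regardless of where its midpoint falls. Distal
regions attach to genes through chromatin interactions
(`link_distal_regions()`): any interaction with either bin overlapping a
gene's proximal region donates every distal region overlapping either of
its bins. Interval arithmetic is delegated to GenomicRanges/IRanges.

## Permissive k-mer motif discovery

`decompose_kmers()` slides a k = 12 window (the typical width of curated
TFBS motifs) over the deduplicated region sequences, strand-specific by
default because downstream scanning covers both strands anyway
(`collapse_rc = TRUE` folds reverse complements). `cluster_hamming()`
forms single-linkage clusters of k-mers at Hamming distance one —
implemented with wildcard buckets and union-find, O(nk), so clusters are
connected components and may chain beyond one mismatch end to end.
`build_ppm()` turns a cluster into a position probability matrix with
count-weighted columns and no pseudocount (regularisation happens at the
log-odds stage). Motifs that resemble a known TFBS are removed
(`filter_known()`), and near-duplicates are collapsed
(`cluster_redundant()`, greedy single linkage at similarity 0.9,
representative = largest summed k-mer count, ties by id).

Motif similarity (`motif_similarity()`) is the mean per-column Pearson
correlation over the best gapless alignment, maximised over offsets with
at least `min_overlap = 8` aligned columns and over the reverse complement
of the second motif. Zero-variance columns use a constant-column
convention (r = 1 when equal, 0 otherwise). This is a deliberately simple
statistic in the spirit of motif-comparison tools; it makes no attempt at
their null models, and its thresholds (`r_match = 0.75` against known
motifs, `r_cluster = 0.9` for redundancy) are plain configurable numbers.

## PWM scanning with exact p-values

`ppm_to_pwm()` applies the standard log2-odds transform with a pseudocount
of 1e-4 against an iid background (uniform by default, configurable). The
p-value of a score is the probability that a random background L-mer
scores at least as high, computed exactly by dynamic programming over
column scores discretized at 1e-3 (`score_pvalue()`); discretization is
the only source of error and is bounded by L/2 grid steps. Scanning
(`scan_sequences()`) reports every window on both strands with p-value at
or below 1e-4 (the conventional scanning threshold) and, optionally, score
above a floor; window p-values are computed on the same discrete grid as
the DP so the two are exactly consistent. Windows containing N are
skipped; overlapping hits are all reported because downstream presence
calls only ask whether a region has at least one hit. The score floor is
not a constant: `derive_score_cutoff()` recomputes it as the mean score of
all hits in the regions linked to the top-ranked genes, which is how such
a cutoff should travel to new datasets.

## Monte Carlo enrichment

`presence_table()` reduces hits to a boolean gene x motif matrix per
region class (proximal, distal, or their union), and `mc_test()` compares
the number of target genes carrying a motif with the distribution of that
count over 10,000 size-matched gene sets sampled without replacement from
the comparator set. The p-value is the fraction of iterations whose
sampled count reaches the observed count (ties fall in the tail; no +1
smoothing), and a motif is enriched when p < 0.05 and the observed count
exceeds twice the null mean. Pairs use the same machinery on the AND of
two presence columns; the pair may sit in different regions of the same
gene. Pair universes are unordered by default, with the full ordered
cross-product available (`enumerate_pairs(mode = "cross")`, n^2 pairs
including self-pairs).

Because the statistic is discrete — 22 target genes can only produce 23
observed counts — the empirical-tail p-value is conservative: under an
exchangeable null its rejection rate at the 0.05 level is about 0.031
rather than 0.05. Removing the target genes from the sampling pool (the
procedure as defined) partially offsets this, because a high observed
count depletes the comparator presences and lowers the null counts; the
net null rejection rate at 22 targets is about 0.036. The test is
therefore valid (type I error at or below nominal) but not exactly
calibrated at this discreteness; analyses needing exact calibration should
use larger target sets or report the exact hypergeometric tail, which the
test reproduces to within Monte Carlo noise.

Candidate selection for the reporter library follows the enrichment
results: pairs are ranked by the sum of two ranks (observed target count
descending; null mean ascending; lexicographic ties), TFBS members are
collected along the ranked TFBS:TFBS list while skipping DNA-binding
archetypes already represented, and novel motifs come from the ranked
TFBS:novel list restricted to pairs containing a selected TFBS
(`select_candidates()`). Each selected motif is represented by its most
frequent matched genomic sequence, ties by scan score, then
lexicographically (`representative_site()`).

## Library design

`design_background()` builds the 125-bp synthetic background: draw a
random sequence, scan it against every screened motif, mutate each
position inside a hit window to a different random base, and repeat until
no hits remain (capped at 100 rounds, reproducible for a fixed seed).
`enumerate_designs()` generates the combinatorial library: `n_slots = 3`
slots, each empty or one of m motifs in forward or reverse orientation,
`(2m + 1)^3` assignments including the all-empty background design —
50,653 at the full 18-motif scale. `render_oligo()` lays occupied slots
left to right from the promoter-proximal end, 10-bp background-derived
spacers between sites, background fill to a constant 88 bp. Because empty
slots contribute nothing, assignments that differ only in which slots are
empty render identical sequences; `render_library()` flags these
collisions, and all grammar statistics treat position as
promoter-relative packed order, which is the physically meaningful
coordinate. Controls are tiled from a reference sequence
(`tile_sequence()`, every 88-bp window, first-occurrence deduplication; a
200-bp control yields 113 tiles) and all inserts can be wrapped in
AgeI/SalI sites plus adapters (`add_cloning_flanks()`).

## STARR-seq activity and grammar statistics

`qc_filter()` keeps oligos with DNA count >= 10 in every DNA replicate and
RNA detected in at least 2 of 3 RNA replicates. Counts are normalized to
CPM per replicate, DNA replicates are collapsed to a per-oligo mean, and
activity is `log2(RNA CPM / mean DNA CPM)` per RNA replicate, minus the
same quantity for the motif-free background oligo (`activity()`); the
background oligo is exactly 0 in every replicate by construction, and any
per-replicate scaling of RNA counts cancels. The default unit of analysis
is the per-oligo mean across replicates.

The grammar tests condition on the design table:

* `motif_effect()` — oligos carrying only the motif of interest (1-3
  copies, one orientation) versus oligos with no copy in any orientation;
  Welch t-test, Bonferroni-corrected alpha, and a |Cohen's d| > 0.5 gate.
* `copy_number_fit()` — ordinary least squares of activity on copy count
  over the pure 1/2/3-copy oligos.
* `position_effect()` — among two-distinct-motif oligos, promoter-proximal
  versus promoter-distal placement of the motif of interest; Wilcoxon
  rank-sum.
* `pair_effect()` — oligos composed of exactly the two oriented motifs
  (each 1-2 copies) versus oligos lacking at least one; Welch t + d gate.
* `synergy_test()` — a pair is synergistic only if its |d| is
  significantly greater (one-sided Z on the large-sample SE of d) than the
  stronger single motif's, and its mean activity exceeds the sum of the
  single-motif means. With exactly additive equal-sized effects the second
  criterion sits on an equality and degenerates to a coin flip; the
  procedure is designed to reject dominant-single-motif confounds, not to
  adjudicate exact additivity.
* `order_effect()` — single-copy two-motif oligos in one promoter-relative
  order versus the opposite order; Wilcoxon plus a |mean ratio| > 2 gate.
  This test defaults to replicate-level activity scores: a 3-slot library
  yields only 3 oligos per order for a given oriented pair, and a 3-vs-3
  rank test cannot reach p < 0.05 at any data, whereas 3 oligos x 3
  replicates (9 vs 9) has an attainable minimum two-sided p of
  4.1e-5. Pooling replicates treats them as independent observations;
  replicate correlations beyond the planted noise model would inflate the
  effective type I error, which is why the other tests keep the per-oligo
  unit by default.

All Bonferroni denominators are explicit arguments (`m_tests`, `n_pairs`)
set by the calling family (`motif_effects()` uses the number of oriented
motifs tested); no corrected threshold is hard-coded.

## Synthetic data: what it emulates, and what it does not

Every input has a generator with planted, serialized ground truth:

* `synth_expression()` — log-normal gene baselines, negative-binomial
  counts (dispersion 0.2, a typical bulk RNA-seq spread), 10 target and
  20 background samples by default; planted genes multiplied by
  `fold = 8` in target samples and divided by it in background samples.
  At these settings the planted genes essentially always occupy the best
  specificity ranks; the mu - 4 sigma top set captures ~90% of them,
  because the planted outliers themselves inflate sigma — a structural
  property of the thresholding rule, not a failure of ranking.
* `synth_regulatory_genome()` — one synthetic chromosome per gene with a
  TSS, a promoter-overlapping proximal region, downstream distal regions,
  and loops connecting promoter bins to distal bins; motif consensus
  sites written into regions with class-dependent probability
  (`odds["target"]` vs `odds["comparator"]`).
* `synth_starr()` — DNA counts are negative binomial around a log-normal
  per-oligo representation; expected RNA rates are the realized mean DNA
  CPM times `2^eta`, where eta adds, per distinct oriented motif, its
  planted `beta` once plus `slope` per extra copy, plus `gamma` per
  unordered pair and `delta` per promoter-relative position. The default
  count dispersion is 0.01, calibrated to the replicate agreement of a
  clean reporter assay (CPM correlations ~0.98); at dispersion 0.2 the
  per-replicate activity noise (~0.65 log2 units) would swamp sub-unit
  effect recovery from the 7-oligo in-groups a 3-slot design produces.
  The `rep_effect_sd` option adds per-oligo, per-replicate log2 noise to
  emulate heterogeneous host cells with low replicate correlation.

The generators do not emulate read-level artifacts (UMIs, sequencing
error, mapping ambiguity), genomic sequence composition (GC bias, repeat
content — the background model is iid uniform), overlapping regulatory
regions across genes, or dependence between motif occurrences. Passing the
test suite therefore demonstrates correctness of the statistical machinery
under the stated generative model, not robustness to everything real data
can do.

A note on the single background oligo: subtracting one oligo's measured
activity transfers that oligo's own replicate noise to every score as a
shared offset (about 0.09 log2 units at depth 500). Grand-mean statements
about a library are only meaningful after averaging over that offset;
within-library contrasts (every grammar test above) are unaffected.

## Numerical choices and problem sizes

Discretization granularity for score p-values is 1e-3 (error bound L/2
grid steps, checked against exhaustive enumeration for L <= 6). Ranks use
average ties everywhere. Greedy clustering orders and all tie-breaks are
deterministic (lexicographic by identifier). The random-number protocol
runs every stochastic routine under its own seed and restores the caller's
RNG state.

The test and acceptance workloads run on deliberately reduced scales: 125-
to 729-oligo libraries (2-4 motifs, 3 slots) instead of the full 50,653;
1,000-gene comparator pools; 500-k-mer clustering instances against a
quadratic oracle; 4,000 simulated motifs for null calibration; 500
simulations for the synergy null. These sizes give the oracles and
parameter-recovery checks comfortable statistical resolution while keeping
a full run in the tens of seconds on one CPU.
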
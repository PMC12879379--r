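# regulogic

Tools for dissecting the *cis*-regulatory grammar behind cell-type-specific
gene expression. Starting from a normalized expression matrix and a set of
open-chromatin regions, the package

1. **ranks genes by expression specificity** between a target and a
   background cell population,
2. **curates regulatory regions** (proximal/distal against TSSs) and links
   distal regions to genes through chromatin interactions (BEDPE loops),
3. **discovers novel DNA motifs** by permissive k-mer decomposition and
   Hamming-distance-1 single-linkage clustering, filtered against a known
   TFBS collection,
4. **scans sequences** with log-odds PWMs using exact, dynamic-programming
   score p-values,
5. **tests motifs and motif pairs for enrichment** in the regions linked to
   the top-ranked genes with a Monte Carlo sampling framework,
6. **designs a combinatorial STARR-seq library** — every combination,
   orientation and position of candidate motifs in a fixed number of slots
   embedded in a screened, motif-free synthetic background — and
7. **scores reporter count tables** for orientation, copy-number, position,
   pair, synergy and order effects (Welch t / Wilcoxon, Bonferroni,
   Cohen's d).

A synthetic-data module (`synth_expression()`, `synth_regulatory_genome()`,
`synth_starr()`) generates every input with planted ground truth, so the
entire pipeline is testable without any external download.

## The core quantities

* **Specificity score** — rank genes high-to-low by target-group aggregate
  expression and low-to-high by background aggregate (average ranks on
  ties); the rank sum concentrates near *n*+1 for unspecific genes, and
  the top-ranked set is everything below `mu - 4 sigma` of that
  distribution (comparator: above `mu - 3 sigma`; the gap is a zone of
  exclusion).
* **Motif p-value** — for a PWM score *s*, `P(score >= s)` for an iid
  background L-mer, computed exactly on a 1e-3 score grid. Scanning keeps
  hits with `p <= 1e-4`, optionally above a data-derived mean-score floor.
* **Enrichment** — observed number of top-ranked genes whose linked
  regions contain the motif, versus 10,000 size-matched draws from the
  comparator genes; enriched means `p < 0.05` and fold change `> 2`.
* **Activity score** — per RNA replicate, `log2(RNA CPM / mean DNA CPM)`
  minus the same quantity for the motif-free background oligo.

## Worked example

```r
library(regulogic)

# 1. rank genes by target-cell specificity on simulated expression
sim  <- synth_expression(n_genes = 2000, n_planted = 20, fold = 8, seed = 7)
sets <- rank_genes(sim$expr, sim$sample_group)
length(sets$top)                          # 19
round(c(sets$mu, sets$sigma), 1)          # 1001.0 157.2
sum(sets$top %in% sim$truth$planted_genes) # 19  (all top genes are planted)

# 2. simulate a regulatory genome, link regions, scan, test enrichment
motif <- build_ppm("TGACTCATCCGA", motif_id = "novel1")
gen  <- synth_regulatory_genome(n_genes = 40, n_target = 10,
                                motifs = list(motif),
                                odds = c(target = 0.9, comparator = 0.15),
                                seed = 8)
map  <- build_gene_region_map(gen$regions, gen$tss, gen$interactions)
hits <- scan_motifs(list(motif), gen$sequences, p_thresh = 1e-4)  # 43 hits
pres <- presence_table(map, hits)
target <- names(gen$gene_class)[gen$gene_class == "target"]
comp   <- names(gen$gene_class)[gen$gene_class == "comparator"]
mc_test(setNames(pres[, "novel1"], rownames(pres)), target, comp,
        n_iter = 10000, seed = 9, subject = "novel1")
#> subject observed null_mean p_value fold_change enriched n_iter seed
#>  novel1       10    3.6771       0    2.719534     TRUE  10000    9

# 3. design a 2-motif, 3-slot library and recover a planted effect
designs <- enumerate_designs(c("novel1", "ctrlM"), n_slots = 3)  # 125 oligos
counts  <- synth_starr(designs, effects = list(beta = c("novel1:fwd" = 0.8)),
                       depth = 500, seed = 11)
keep <- qc_filter(counts$dna, counts$rna)
act  <- activity(cpm(counts$dna)[keep, ], cpm(counts$rna)[keep, ],
                 designs$oligo_id[designs$is_background])
motif_effect(act, designs, "novel1", "fwd", m_tests = 4)
#>    subject n_in n_out  mean_in mean_out       p_raw cohens_d significant
#> novel1:fwd    7    27 0.834567 -0.02948 5.95405e-09  9.87842        TRUE
```

The observed 10 of 10 target genes versus a null mean of 3.7 comparator
genes gives fold change 2.7 at Monte Carlo p = 0 — the planted motif is
called enriched. The reporter analysis recovers the planted +0.8 log2
activity shift as `mean_in - mean_out = 0.86` with an overwhelming Welch
p-value.

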
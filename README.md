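# xtalksig

Pathway cross-talk gene signatures from case/control expression,
interaction networks and pathway gene sets.

Diagnostic gene signatures built from differential expression alone tend
to ignore how genes act together. `xtalksig` implements a network- and
pathway-aware alternative for two-group (tumor/control) expression
cohorts, aimed at computational biologists who want every stage of such
a design testable and reproducible:

1. **Differential expression** — per-sample standardization, then a
   two-group empirical-Bayes moderated *t* (raw *p* < 0.05 and
   |log2FC| > log2 1.5).
2. **Disease-specific subnetwork** — DE genes plus every gene with ≥ 5
   direct interactions with them in a background network (union of
   two-column edge lists), as a full induced subgraph.
3. **State scores** — per gene, W = E·D: E is the mean signed deviation
   of tumor samples outside the control interval [μ−σ, μ+σ], D the
   subnetwork degree. Genes with W ≠ 0 are the *important* genes,
   up (W > 0) or down (W < 0).
4. **Pathway activity** — hypergeometric enrichment (BH, q < 0.05) of
   the up/down important genes over a GMT collection; per-sample score
   ln(Σ_up (d−μ)² / Σ_down (d−μ)²), active if positive; hierarchical
   clustering of samples on the scores.
5. **Cross-talk signature** — genes shared by ≥ 2 enriched pathways,
   reduced to ≤ 45 genes by correlation-based feature subset selection
   (CFS merit k·r̄_cf / √(k + k(k−1)·r̄_ff), best-first forward search).
6. **Evaluation** — 500-tree random forest (70% case subsampling, 30%
   feature subspace, vote-fraction scores), ROC/AUC on a held-out
   cohort, a permutation null of random same-size gene sets, and
   Kaplan–Meier/log-rank survival stratification of patients tagged
   *altered* on the signature.

A first-class synthetic-data module generates expression matrices,
preferential-attachment networks, overlapping gene sets and clinical
tables with planted truth, so recovery of every stage is measurable
without any external download. See the methods vignette
(`vignettes/crosstalk-signature-methods.Rmd`) for the models, defaults
and design decisions.

## Worked example

The repository is organised as an analysis workflow: numbered scripts
under `analysis/` drive the package functions and write their tables
under `results/analysis/`.

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_differential_expression.R
Rscript analysis/03_network_state_scores.R
Rscript analysis/04_pathway_activity.R
Rscript analysis/05_crosstalk_signature.R
Rscript analysis/06_classifier_evaluation.R
Rscript analysis/07_survival_stratification.R
```

Output of the run above (seed 1, the default study conditions: 2000
genes, 60 vs 60 samples per cohort, 50 up + 10 down genes planted at
|log2FC| = 1, noise sd 0.5):

```
flagged 60 genes (50 up, 10 down)
recall of planted genes: 1.000; false-positive rate: 0.0000

disease-specific subnetwork: 95 nodes (37 introduced), 373 edges
planted neighbors recovered: 1.00
important genes (W != 0): 93 of 95 scored (61 up, 32 down)
state-score sign concordance with planted direction: 1.000

enriched pathways: 6 (1 both, 5 up-only, 0 down-only)
median pathway score, tumor vs control: 2.26 vs 0.57
two-group clustering agreement with labels (ARI): 1.000

genes in >= 2 enriched pathways: 8 (of 10 designated: 0.80 recovered)
signature: 8 genes, CFS merit 0.949

held-out AUC of the 8-gene signature: 0.998
permutation p-value (null >= observed): 0.000 (strict >: 0.000)

tagged 76 altered / 124 unaltered patients
log-rank: chi-square 9.12, p = 0.0025
```

Reading the numbers: all 60 planted genes are re-called with no false
positives; the subnetwork recovers every planted well-connected
neighbor; 93 of 95 subnetwork genes receive a nonzero state score and
every scored planted gene gets the planted sign. Eight of the ten
designated cross-talk genes survive to the signature (the other two sit
isolated in the subnetwork, so W = 0 excludes them — the multiplicative
rule at work). The signature separates the held-out cohort almost
perfectly, none of 100 random same-size gene sets reaches its AUC, and
patients tagged altered on the signature have significantly shorter
survival at the planted hazard ratio 2.5.

The same workflow runs as one call with per-stage artifacts and a JSON
manifest:

```r
library(xtalksig)
res <- run_pipeline(pipeline_config(seed = 1, outdir = "results/run1"))
res$roc$auc
```

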
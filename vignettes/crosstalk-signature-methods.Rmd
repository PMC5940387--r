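---
title: "Cross-talk gene signatures: models, scores and design choices"
author: "xtalksig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-talk gene signatures: models, scores and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xtalksig)
```

## The problem

A recurring design in cancer transcriptomics is to look for a compact gene
signature that (i) distinguishes tumors from normal tissue and (ii) carries
prognostic information. `xtalksig` implements one such design for
case/control expression cohorts: differential expression seeds a
disease-specific protein-interaction subnetwork; each subnetwork gene is
scored by how far tumors push it outside its normal expression range,
weighted by its connectivity; pathways enriched in the resulting
"important" genes are scored per sample; genes sitting in two or more
enriched pathways — *cross-talk genes*, putative mediators of
inter-pathway signalling — are reduced to a signature, which is then
stress-tested with a random-forest classifier, a random-gene-set
permutation null, and survival stratification.

All stages run on synthetic data with planted truth, so every claim the
package makes about recovery and discrimination is measurable.

## Models and scores

**Differential expression.** Samples (columns) are z-scored
(`standardize()`; sd with the $n-1$ denominator), mirroring the common
practice of standardizing microarray intensity profiles before testing.
Each gene is tested with a two-group moderated $t$: gene-wise pooled
variances $s_g^2$ on $d$ degrees of freedom are shrunk toward a prior
variance $s_0^2$ estimated from all genes,

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d},$$

with $(d_0, s_0^2)$ obtained by moment-matching the log sample variances
against the scaled inverse-$\chi^2$ model, and the statistic referred to a
$t$ distribution on $d + d_0$ degrees of freedom. A gene is called when
the **raw** $p < 0.05$ and $|\log_2\mathrm{FC}| > \log_2 1.5$; the rule
names a plain p-value, so Benjamini–Hochberg q-values are reported but do
not gate the call. Because the matrix is on the log2 scale, the fold
change is the difference of group means. `prior_df = 0` recovers the
ordinary pooled $t$ exactly, which the tests use as a limit-case oracle;
the full statistic is cross-checked against the established
empirical-Bayes implementation on heteroscedastic data.

**Disease-specific subnetwork.** The background network is the union of
two-column edge lists (symbols upper-cased, self-loops dropped,
undirected duplicates merged). The subnetwork keeps every called DE gene
plus every other gene with at least `min_links = 5` direct background
interactions with DE genes, and takes the *full induced subgraph* on that
node set — including edges between two introduced genes. The reported
node/edge counts of the motivating design cannot disambiguate this
choice, so the standard induced-subgraph convention is used.

**State score.** For gene $g$, control samples define an interval
$[N, M] = [\mu - \sigma,\ \mu + \sigma]$. A sample's deviation is
$E = 0$ inside the interval, $\exp - M$ above and $\exp - N$ below —
signed and continuous. One textual branch of the source description
("E = exp − N when exp was less than M") contradicts its own zero case
inside the interval; it is read as "less than $N$", the only reading that
keeps $E$ well defined, and documented here rather than silently fixed.
The per-gene $E$ is the mean deviation over tumor samples (the median is
available), $D$ the degree within the subnetwork, and $W = E \cdot D$.
Genes with $W \neq 0$ form the important set, up- or down-regulated by
the sign of $W$. An isolated gene ($D = 0$) has $W = 0$ and is dropped
whatever its deviation — the multiplicative rule, not a judgement about
the gene; this is also why the important set is slightly smaller than the
subnetwork.

**Pathway activity.** Up and down important genes are separately tested
for enrichment over a GMT collection with the one-sided hypergeometric
tail $P(X \ge k)$ and BH correction ($q < 0.05$). Enriched pathways carry
their up and down member hits, and each sample gets

$$\mathrm{score} = \ln \frac{\sum_{i=1}^{m} (d_i - \mu_i)^2}
                            {\sum_{j=1}^{n} (d_j - \mu_j)^2},$$

with $\mu$ the control mean of the gene. Positive scores are an *active*
pattern, negative *inactive*. Pathways with no up (or no down) members
would make the ratio undefined; the empty sum is replaced by
`eps = 1` (configurable) — the chief interpretive decision of this stage,
since the source formula is silent about single-direction pathways. A
zero numerator against a positive denominator is guarded at the sentinel
$\pm 745$ (the edge of double-precision $\exp$) with a warning. The
natural logarithm is used; the source writes "log" without a base.

**Sample clustering.** Samples are clustered on the pathway-score matrix
with Euclidean distance, cut at two groups, and the agreement with the
true labels is reported as the adjusted Rand index. Two details depart
from the most naive setup, both for documented reasons. Rows are
standardized before the distance (`scale_rows = TRUE`), the convention
of expression heatmaps: pathway scores have strongly heterogeneous
variances — a one-gene denominator is $\chi^2_1$-noisy — and without
row scaling the distance follows the noisiest pathway instead of the
disease contrast (on planted data, ARI ≈ 0 raw versus 1.0 row-scaled).
And the default linkage is Ward's minimum-variance criterion rather
than complete linkage: when the tree is *cut into two groups*, the
complete-linkage cut regularly isolates one or two outlying samples and
leaves everything else in one block (observed on planted data: ARI ≈ 0
for a 2 + 118 split that Ward resolves at ARI ≈ 0.97–1.0), whereas
Ward's criterion targets compact, balanced groups. Complete linkage
remains available via the `method` argument.

**Cross-talk genes and CFS selection.** A gene belonging to at least two
enriched pathways' member lists is a cross-talk gene; counting uses the
directional member lists (the genes that triggered enrichment), not the
full set definitions. The signature is chosen by correlation-based
feature subset selection with merit

$$\mathrm{merit}(S) = \frac{k\,\overline{r}_{cf}}
  {\sqrt{k + k(k-1)\,\overline{r}_{ff}}},$$

where $\overline{r}_{cf}$ is the mean absolute point-biserial correlation
of the $k$ subset genes with the tumor/control label and
$\overline{r}_{ff}$ the mean absolute pairwise correlation within the
subset. The forward search follows the canonical best-first behaviour:
it always adds the merit-maximizing candidate but tolerates up to
`patience = 5` consecutive non-improving additions before stopping, and
returns the best-merit prefix, capped at `max_size = 45`. A strictly
greedy stop (`patience = 0`) stalls far below the cap on realistic data
because merit increments shrink beneath correlation sampling noise; the
tolerance is the standard remedy, not a tuning knob. Note one algebraic
corner: a *perfect* duplicate ($r_{ff} = 1$) leaves the pair merit equal
to — not below — the singleton merit; only imperfectly redundant genes
are actively penalized.

**Classifier evaluation.** A 500-tree random forest is grown on the
signature, each tree on a 70% subsample of training cases (without
replacement) and each split over a random 30% of the features; a sample's
score is the fraction of trees voting tumor. Although the motivating
description says "regression" forest, the model is used to distinguish
two classes, so the vote fraction is the natural continuous score. ROC
curves come from a threshold sweep whose trapezoid AUC equals the
midrank Mann–Whitney statistic (asserted exactly in tests). Genes absent
from a test cohort are imputed at the training control mean rather than
dropped, keeping the feature space stable. Significance is a permutation
null: `B` random gene sets of the signature's size, drawn from the genes
common to both cohorts, each trained and evaluated identically;
$p = \#\{\mathrm{null} \ge \mathrm{observed}\}/B$ (ties count against
significance; the strict-inequality variant is also reported). The
reference configuration uses `B = 100`; 1000 is available by
configuration.

**Survival stratification.** A patient is *altered* when any signature
gene satisfies $|z| \ge z_{\mathrm{cut}}$ against the reference
(training-control) distribution, boundary inclusive — an explicit,
documented stand-in for a web-portal alteration call whose definition is
not recoverable. The function default is $z_{\mathrm{cut}} = 2$; the
pipeline default is 3, because with a 45-gene panel a per-gene 2-sd rule
tags $1 - 0.954^{45} \approx 88\%$ of null patients altered and destroys
the contrast, whereas 3 sd keeps the false-tag rate near 11% — a
multiplicity argument, fixed before any evaluation. Groups are compared
with Kaplan–Meier curves and the standard two-group log-rank
$\chi^2_1$ test.

## The synthetic generators

The generators define the reference study conditions (all defaults in
`pipeline_config()`):

* **Expression**: 2000 genes, 60 tumor / 60 control per cohort; 50 up and
  10 down genes planted at $|\log_2\mathrm{FC}| = 1$, within-group sd
  0.5; per-gene baselines $\mathcal N(8, 1)$ on the log2-intensity scale.
  The baseline spread matters: per-sample standardization divides by the
  column sd ($\approx \sqrt{1 + 0.25}$), so a planted unit fold change
  stays above the $\log_2 1.5$ threshold. A much wider baseline spread
  would shrink standardized fold changes below the threshold — a real
  phenomenon of scale standardization worth remembering with real data.
  Validation and survival cohorts reuse the training cohort's planted
  genes and baselines with fresh noise and samples.
* **Network**: 10000 edges over the 2000 genes (mean degree 10, of the
  order of curated protein-interaction networks); 20 designated non-DE
  neighbors are first guaranteed $\ge 5$ links to distinct planted DE
  genes, then the budget is filled by preferential attachment
  (probability $\propto$ degree + 1), giving the heavy-tailed degree
  distribution in which hub genes exist.
* **Gene sets**: 6 sets of 20 genes; 10 designated shared genes placed in
  exactly two sets each; every other member in exactly one set, so the
  designated genes are provably the only cross-talk genes. Sets are
  direction-coherent (5 sets fill from the up pool, 1 from the down pool,
  the planted 50:10 proportion): real pathway collections are mostly
  single-direction, and a mixed set makes the log-ratio score cancel its
  own signal between numerator and denominator.
* **Survival**: 100 altered / 100 unaltered patients; exponential event
  times with baseline rate 1/1000 per day and hazard ratio 2.5 for the
  altered group; censoring flags drawn independently at 20% — the
  simplest model consistent with a log-rank evaluation.

What the generators deliberately do **not** emulate: probe-level
summarization, platform or batch effects, correlated co-expression
modules beyond the class signal, informative censoring, and annotation
noise in gene sets. Passing tests therefore demonstrate that the
implementation recovers structure it is told is there under clean noise
— they do not certify performance on real cohorts, where fold changes,
network ascertainment bias and pathway curation are all messier.

## Numerical choices and degenerate inputs

* sd uses the $n-1$ denominator everywhere, matching `standardize()`.
* Zero-variance sample columns abort standardization with the sample
  named; zero-variance genes in CFS get correlation 0 with a warning;
  zero reference sd in alteration tagging skips the gene with a warning.
* The pathway-score sentinel is $\pm 745$; `eps = 1` substitutes empty
  member sums.
* Selection ties in the CFS search break on the gene symbol; all
  stochastic stages (generators, forest, permutation) take explicit
  seeds, and the pipeline fans a single master seed into fixed per-stage
  child seeds (`derive_seeds()`), so stage reruns and whole-pipeline
  reruns are byte-identical.
* The log-rank test with no events in either group returns statistic 0,
  p 1, with a warning instead of failing.

## Problem sizes

The reference configuration (above) runs the whole pipeline in well
under a minute on one CPU, with the permutation null at `B = 100`. The
test suite scales some replicate counts (e.g. power checks over 30
seeds, calibration over 200 replicates) to keep a full run in the
low minutes; these sizes are stated where they are used and were chosen
as the smallest giving stable verdicts for the properties asserted.

## Known limitations

* The important-gene rule is $W \neq 0$; the source pipeline evidently
  applied an additional unstated filter (its subnetwork-to-important drop
  cannot be reproduced exactly), so an optional $|W|$ rank cutoff is the
  only extra control offered.
* Single-direction pathway scores depend additively on `eps`; their
  *ordering* across samples does not, which is what the clustering uses.
* The alteration tag is an expression z-score rule, not a mutation or
  copy-number call; concordance with the planted alteration status is
  reported so the tag's noise is visible rather than hidden.
* With very small candidate pools the CFS search can return fewer genes
  than `max_size`; that is the search's judgement, not an error.
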
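---
title: "Methods: hypoxia-regulated prognostic lncRNA screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hypoxia-regulated prognostic lncRNA screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncscreen)
```

## The problem

Hypoxic lung adenocarcinomas (LUAD) are more aggressive, and part of that
aggressiveness runs through the tumor stroma — in particular lymphatic
vessels. `lncscreen` implements a cohort-level screen that nominates long
noncoding RNAs (lncRNAs) which are (i) associated with the tumor's hypoxic
status, (ii) associated with poor overall survival, and (iii) inducible by
hypoxia in vitro, and then asks, in single-cell data, whether a nominated
transcript is actually expressed by tumor cells at all or is confined to one
stromal population (lymphatic endothelial cells, LEC, marked by PROX1, PDPN
and CDH5).

Every stage is exercisable on seeded synthetic data with known ground truth,
which is how the package validates itself end to end.

## Hypoxia status: a counting metagene score

Tumor hypoxic status is scored a posteriori from a 27-gene hypoxia metagene.
For each signature gene, expression is back-transformed to the linear scale
(`2^x`; inputs are log2 intensities), the baseline is the arithmetic mean
over the healthy samples, and the tumor's fold change is the ratio to that
baseline. The score of a tumor is the **count** of signature genes with fold
change strictly greater than 2. With the full signature, scores 0–14
classify the tumor **Low** and 15–27 **High**.

Numerical conventions worth stating:

* Both cutoffs are strict (`FC > 2`; High iff `score >= 15`). A gene at
  exactly FC 2 does not count.
* A score of 0 is classified Low. The published band is printed "from 1 to
  27", leaving score 0 formally unaddressed; zero induced genes is minimal
  hypoxia, so Low is the only sensible reading.
* When a platform lacks some signature genes, `compute_fold_changes()`
  tolerates gaps down to a coverage of 0.8 (configurable) and
  `hypoxia_score()` rescales the High threshold proportionally
  (`ceiling(15 * G / 27)`), reporting the rescaling. Below the coverage
  floor the score errors rather than silently shifting the class boundary.

Association of an individual transcript with hypoxic status ("hypoxic status
pca" in the screen) is operationalized as the Spearman rank correlation of
the transcript with the integer score across tumors (mid-ranks for ties;
two-sided p from the t approximation `t = rho * sqrt((n-2)/(1-rho^2))`),
BH-adjusted across the screened transcript universe. Zero-variance inputs
are flagged undefined, never coerced to rho = 0.

## Stroma and immune content: cumulative z-scores

Per-sample stroma/immune content is proxied by the cumulative z-score of a
141-gene signature: `Z_s = sum_g (x_gs - mean_g) / sd_g`. The reference set
for `mean_g`/`sd_g` defaults to **all** cohort samples; since the source
description says only "base mean of gene", the healthy-only alternative is
exposed via `reference_samples`. sd is the unbiased (n−1) estimator — any
consistent choice merely rescales each gene's term. Genes with zero sd over
the reference set are dropped with a warning. Candidate-vs-score
correlations use the Pearson product-moment test.

## Survival screening

Overall-survival association is screened by splitting tumors into expression
**quartiles** (linear-interpolation percentiles; ties go to the lower group,
so assignment is deterministic and the cut points are recorded) and testing
the four groups with the unweighted Mantel–Haenszel log-rank test
(`survival::survdiff` behind the module surface; Kaplan–Meier curves via
`survival::survfit`). Quartiles rather than a median split are the default
because the published survival figures are quartile analyses; `n_groups = 2`
is available. The recurrence analysis is a Wilcoxon rank-sum comparison of
expression by recurrence status, matching the published boxplot tests.

## Differential expression and threshold dialects

Where the original workflow used limma/DESeq2, only thresholded DEG sets are
consumed downstream, so the package uses a deliberately simple per-gene
Welch t on log2 values (`two_group_de()`; sign convention: treatment minus
control) with BH adjustment. The backend sits behind a module boundary and
can be swapped. Two published threshold dialects are kept explicit, never
inferred:

* xenograft-style: log2 intensity > 6, |log2FC| > 0.5, **adjusted** p < 0.05;
* LEC-knockdown-style: intensity > 5, |log2FC| > 0.5, **raw** p < 0.05.

All threshold comparisons are strict inequalities; a gene at |log2FC| = 0.5
exactly is excluded.

## The three-criterion screen and its presets

`evaluate_criteria()` fills, per transcript: tumor/healthy log2 ratio and
FDR, mean log2 intensity over tumors, Spearman association with the hypoxia
score (BH across the universe), quartile log-rank OS p, and the in-vitro
contrast statistics. Flags are pure functions of these statistics and the
thresholds; `intersect_candidates()` does the set algebra (Venn counts
consistent by inclusion–exclusion) and orders the final triple intersection
by hypoxia-association p.

The source material states two threshold dialects for the hypoxia criterion,
and their intent cannot be merged without guessing, so both ship as named
presets:

* **figure-strict** (default): intensity > 6 and hypoxia-association
  adjusted p < 0.001 — the figure-legend wording.
* **methods-loose**: additionally tumor/healthy ratio ≥ 1.6-fold with
  FDR < 0.05, and adjusted p < 0.05 — the methods-section wording.

Under the generator's default couplings the two presets behave differently
in an instructive way: the planted candidate couples to latent hypoxia with
slope 1.0 in log2 units, so its *mean* tumor/healthy shift is about 0.5 log2
(~1.4-fold), below the 1.6-fold ratio rule — the methods-loose preset
therefore rejects it while figure-strict accepts it. Real screens presumably
involved transcripts with larger baseline shifts; the generator keeps the
coupling moderate so that the association criterion, not a trivial mean
shift, carries the screen.

Transcripts absent from the cohort matrix or the in-vitro table are flagged
`missing` and excluded from set algebra rather than silently counted false.

## Single-cell restriction

QC follows the standard droplet rules: remove ribosomal genes (RPL/RPS
prefixes), genes detected in fewer than 3 cells, cells with fewer than 200
detected genes, more than 7500 detected genes, or more than 5% mitochondrial
counts (MT- prefix, configurable). Boundaries are strict as quoted: exactly
200 features or exactly 5% mitochondrial is retained. Removal is iterated to
a fixed point so `qc_filter()` is idempotent (dropping cells can push genes
below the 3-cell floor); per-rule counts are reported from the first pass.
Clustering is **consumed, not computed**: cluster labels arrive as
annotations, as when reusing a dataset's published clustering.

Normalization is per-cell library-size scaling to 10,000 followed by
`log1p` — the common default of the named single-cell toolchain, whose
parameters the source does not state. For restriction scoring, cluster
means are taken on the **linear** normalized scale (`normalize_log(log =
FALSE)`), the same convention dot-plot "average expression" uses: on that
scale the top-cluster/next-cluster ratio keeps its "times more expressed"
meaning, and a transcript planted at count-fold F over other clusters yields
a fold estimate near F. On log-transformed means the same planted fold
compresses to roughly half, which would make the 10-fold gate
uninterpretable.

The restriction score of a transcript is
`score = max(cluster means) / sum(cluster means)` (1 = fully confined,
1/k = uniform over k clusters), with the fold over the next-best cluster and
the Pearson concordance between the transcript's cluster-mean profile and
each marker's profile. A transcript is reported **restricted** when
`score > 0.5` and `fold >= 10`; the 10-fold gate mirrors the magnitude
reported for LEC-confined transcripts but is configurable, since that
published magnitude mixes qPCR and single-cell evidence.

## The synthetic study generator

`sim_params()` fixes the study conditions; all three generators draw from a
single seeded generator per call and are bit-reproducible. The defaults:

* **Cohort**: 11 healthy / 57 tumor samples (the motivating cohort's size);
  27 hypoxia program genes with log2 effects Uniform(1.2, 2.5) scaled by a
  latent per-tumor hypoxia h ~ Uniform(0, 1) (healthy tissue at h = 0);
  baselines Uniform(4, 10) log2; residual noise sd 0.3. These effect sizes
  make the count score separate h < 0.2 from h > 0.8 essentially perfectly
  while mid-range tumors are genuinely ambiguous — the Low/High boundary is
  meaningful, not degenerate.
* **Confounders**: an LEC fraction ~ Beta(2, 20) (a few percent of stromal
  lymphatic content) driving a 141-gene stroma program and a PROX1-like
  marker (intercept 4, slope 10, so marker and fraction correlate strongly);
  an immune fraction ~ Beta(2, 5) driving the 141-gene immune program.
* **Planted candidate** (`LNC0001`, baseline 7 log2 so intensity criteria
  are attainable): hypoxia coupling alpha_h = 1.0; LEC-fraction coupling 4
  (bulk expression partly reflects lymphatic content, the confounding the
  single-cell stage is there to resolve); immune coupling −1.5 (an inverse
  immune association); log-hazard gamma = 0.8 per sd of expression.
* **Survival**: exponential times with hazard `lambda0 * exp(gamma * z)`,
  `lambda0 = log(2)/1500` per day (median ~4 years at average expression),
  censoring Uniform(0, 3650 days) plus the administrative horizon — roughly
  half the tumors yield events. Exponential rather than Weibull keeps
  closed-form sanity checks simple.
* **In vitro**: 5 replicates per arm, log2 noise sd 0.25; under hypoxia the
  27 program genes shift by their full-program effects, a CA9-like positive
  control by 3 log2, and the candidate by 2.0 log2 (a strong four-fold
  induction, consistent with qPCR-scale inductions of hypoxia-responsive
  lncRNAs). Five replicates and a 2.0 log2 effect were chosen so that the
  candidate clears the *BH-adjusted* in-vitro criterion across a ~800-gene
  universe in well over 95% of seeds: with 3 replicates (t on ~4 df) the
  same criterion is near coin-flip power, which would make screen validation
  a test of luck rather than of code.
* **Single cell**: 800 cells x 9000 genes (the gene count exceeds the
  7500-feature doublet rule so that rule is exercisable), six clusters
  including LEC (10%); negative-binomial counts (size 2) around per-cluster
  means with log-normal library factors; PROX1/PDPN/CDH5-like markers at
  mean 5 in LEC vs 0.05 elsewhere; the query transcript at count-fold 20
  over non-LEC clusters; 2% of cells planted per QC rule, each violating
  exactly one rule by a wide margin (so the filter's removed set equals the
  planted set without cascades), plus 30 genes planted in < 3 cells and 20
  ribosomal-prefixed genes.

What the generator does **not** emulate: microarray probe-level noise, batch
effects, doublet expression profiles (the feature-ceiling violators are just
high-complexity cells), cluster-assignment errors, or dependence between
transcripts beyond the planted programs. Passing tests therefore show the
pipeline recovers known structure under its own model assumptions, not that
the thresholds are optimal for any particular real platform.

## Statistical power at the two cohort scales

A fact worth knowing before pointing the screen at a small cohort: at the
57-tumor scale, a transcript with the default planted coupling reaches a
hypoxia-association rho around 0.5, i.e. an adjusted p near 0.01 across a
500-transcript universe — short of the figure-strict 0.001 cut in ~95% of
seeds. The screen's validated recovery regime is 200–300 tumors, where
recovery of the planted triple-positive is essentially perfect and the
expected number of false triple-positives among 500 null decoys is far below
one. `run_pipeline()`'s synthetic mode and the screening-scale analysis
scripts use 250 tumors for this reason; the 57-tumor design is still
generated and scored to illustrate the cohort-scale behavior.

## Known limitations

* The Welch-t DE stage ignores variance moderation; with 2–3 replicates its
  power is well below that of an empirical-Bayes test.
* The hypoxia score presumes log2 input and a healthy baseline from the same
  platform; no cross-platform normalization is attempted.
* Gene matching is exact and case-sensitive; no alias resolution.
* The 27- and 141-gene fixture lists carry real human gene symbols of the
  right biology but are configurable stand-ins, not the original published
  identities; swap in project lists via `read_signature()`.
* The restriction score compares cluster means only; it does not model
  within-cluster heterogeneity or ambient RNA.
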
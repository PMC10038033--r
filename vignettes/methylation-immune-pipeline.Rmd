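---
title: "From promoter methylation to tumour immunity: models and design"
author: "methylImmune"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From promoter methylation to tumour immunity: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylImmune)
```

## The analysis in one paragraph

methylImmune links aberrant promoter DNA methylation to the tumour immune
microenvironment. Starting from an Illumina 450K-style beta-value matrix
(per-CpG methylated intensity fraction `M/(M+U)` in [0,1]) it (i) calls
CpG sites differentially methylated between tumour and normal samples,
(ii) asks, gene by gene, whether promoter methylation predicts expression
by multiple linear regression, (iii) condenses each gene into a signed
regulation score `RS = -log10(p) * sign(delta)` and feeds the resulting
ranking to a pre-ranked gene-set enrichment engine, (iv) computes three
per-sample immune response scores (MHC, CYT, CTL), (v) groups tumours
into methylation subtypes by resampling consensus clustering, (vi) builds
CpG risk scores for survival with a maximally selected log-rank cutoff,
and (vii) extracts hub genes from a seed-anchored protein-interaction
network. Every stage can be exercised on synthetic data with planted,
recorded ground truth.

## Quantification and preprocessing

Beta values are `M/(M+U)`; a cell with `M + U = 0` has no defined
methylation level and is recorded as missing rather than given a
fabricated value. Probes on the sex chromosomes and probes overlapping
SNPs are unstable across individuals and removed outright (the manifest
SNP flag is used; no distance window is applied). A probe is retained
only if its missing fraction across samples is strictly below 0.4, and
remaining missing cells are filled with the probe's across-sample mean,
computed jointly over tumour and normal samples — so imputation leaves
each probe's observed mean untouched and the filter/impute composition is
idempotent. Promoter regions are the union of the 1stExon, 5'UTR, TSS1500
and TSS200 transcript annotations; Body and 3'UTR probes never enter
promoter-level summaries. Genomic positions are 1-based manifest
coordinates and are used only for ordering probes within a gene.

## Differential methylation

Per probe, a two-sample t-test between tumour and normal betas with a
joint gate: `hyper` needs `p <= 0.05` and `delta >= 0.1`, `hypo` needs
`p <= 0.05` and `delta <= -0.1`, where `delta` is the tumour mean minus
the normal mean. Welch's unequal-variance test is the default because
tumour and normal group sizes are typically very unbalanced; the pooled
t-test is one flag away (`varEqual = TRUE`) and the two differ little at
the effect sizes that pass the delta gate. Probes with zero variance in
both groups are given `p = 1` to avoid NaN propagation. No CpG-level
multiple-testing correction is applied by default — the raw-p plus
effect-size gate is the conventional criterion here and the delta gate
makes it conservative in practice (the synthetic null suite measures a
false-positive rate far below 5%); a BH-gated variant is available via
`adjust = "BH"`. Context summaries split a multi-label probe fractionally
(1/k to each of its k region labels) so totals are preserved.

## Promoter regression and the RS ranking

For gene *g* with promoter probes *P*, expression (log2(RPKM+1)) is
regressed on the promoter betas by OLS, and the per-gene significance is
the overall F-test p-value: the workflow reports one p per gene, which
implies a model-level test rather than per-coefficient tests. The fit
uses tumour samples only by default — the tumour/normal contrast is
already carried by `delta`, and pooling conditions would let the
tumour/normal shift masquerade as a within-tumour association
(`samples = "all"` restores pooled fitting). Perfectly collinear probes
are dropped from the design via the QR rank before fitting; genes with
`n <= p + 1` are skipped.

The ranking statistic is `RS = -log10(p) * sign(delta)`. The log base is
10: it matches the p-threshold framing, and any base only rescales ranks
monotonically, so enrichment results are unchanged. `p = 0` is floored at
1e-300 to keep ranks finite but extreme; `delta = 0` gives `RS = 0`. Ties
in the ranking are broken alphabetically so rankings are reproducible
across platforms.

## Pre-ranked enrichment

The engine is a from-scratch weighted Kolmogorov–Smirnov running sum:
walking the ranking, set members increment the sum by
`|rs|^weight / sum(|rs|^weight over members)` and non-members decrement
it by `1/(N - m)`; the enrichment score is the signed extremum (an exact
positive/negative tie resolves to the positive peak). `weight = 1` is the
default, matching the usual "weighted" pre-ranked setting; `weight = 0`
reduces to the classic unweighted KS statistic, and the test suite
asserts both the exhaustive brute-force equivalence and agreement with
fgsea's `calcGseaStat` as an independent reference.

The null is gene-label permutation at fixed set size — the only null
available to a pre-ranked analysis. NES normalises the observed ES by the
mean |null ES| of matching sign (positive and negative nulls separately),
the nominal p is the one-sided sign-matched permutation fraction with
add-one smoothing (minimum p = 1/(nPerm+1); the default nPerm = 1000
gives p-resolution of about 0.001 at desk-scale runtime), and the
adjusted p is Benjamini–Hochberg across sets by default with a
permutation FDR-q alternative (`fdr = "qvalue"`). Under a random set the
engine is self-normalising: |NES| concentrates near 1 and the nominal p
is uniform, which the acceptance suite checks over 200 replicates.

## Immune scores

MHC is the mean log2(RPKM+1) expression of the nine-gene MHC-I core panel
(HLA-A, HLA-B, HLA-C, B2M, TAP1, TAP2, PSMB8, PSMB9, NLRC5); CYT is
`(GZMA + PRF1)/2`; CTL is `(GZMA + GZMB + PRF1)/3`. The MHC panel
degrades gracefully (mean over available genes, with a warning) because
nine constituents leave redundancy; CYT and CTL hard-fail on a missing
gene because two or three constituents leave none. Matching is exact,
case-insensitive symbol matching; alias resolution is out of scope.

## Consensus subtypes

Tumour samples are clustered on the beta values of the differential
probes (which probes feed the clustering is configurable; differential
probes are the default). Each of `nResamples` iterations draws 80% of the
samples without replacement, clusters them, and the consensus matrix
accumulates the fraction of co-draws in which two samples co-clustered.
The base clusterer is k-means with multiple restarts: it is fast and
fully deterministic under the master seed; average-linkage hierarchical
clustering is available via `clusterer = "hclust"` and satisfies the same
co-occurrence contract. Final labels cut an average-linkage tree on
`1 - consensus` at k. k is a user input (four in the motivating KIRC
analysis); `consensusSweep()` reports the consensus-CDF area over a range
of k to aid the choice. Degenerate resamples (fewer distinct points than
centres) are redrawn.

Subtype comparisons of mean methylation, immune scores and TMB use
two-sided Wilcoxon rank-sum tests per cluster pair (exact where sizes
permit, mid-rank normal approximation otherwise), reporting the direction
of the median difference; clusters with fewer than two samples are
excluded.

## Survival

Risk scores are linear CpG combinations `sum(coef * beta)`. Coefficients
either come from a multivariate Cox proportional-hazards fit (Efron tie
handling, via the survival package) or are supplied externally, e.g. a
published five-CpG model, in which case no fitting occurs. The cutoff
dichotomising the scores maximises the absolute standardized log-rank
statistic over all candidate splits leaving at least `minProp = 0.1` of
samples on each side, with ties resolved toward the more balanced split.
The log-rank p at that cutoff is reported as `p_naive` and is knowingly
anti-conservative — the cutoff was selected to maximise the statistic —
so `maxstatCutoff()` can additionally compute a permutation-corrected p
(maximum statistic under label permutation): fidelity to the common
workflow first, an honesty flag second. Kaplan–Meier curves are the
product-limit estimator; with no censoring they coincide exactly with the
empirical survival function, which the tests assert.

## PPI hubs

The network keeps exactly the background edges touching at least one seed
gene ("pairs interacting with seed nodes"); neighbor–neighbor edges are
excluded by default, with `induced = TRUE` for the full induced subgraph.
Storage is simple and undirected: no self-loops, one copy per unordered
pair, and the handshake identity `sum(degree) = 2|E|` is enforced by the
class validity. Hubs are nodes of degree >= 10 by default, ordered by
degree then symbol for reproducible reports.

## What the synthetic generator emulates — and what it does not

Baseline probe methylation is a mixture of Beta(2, 8) (hypomethylated
pool, truncated to <= 0.5) and Beta(8, 2) (hypermethylated pool,
truncated to >= 0.7), reproducing the bimodal methylome of 450K arrays.
Planted hypermethylation is applied to low-pool probes and planted
hypomethylation to high-pool probes, where such shifts are observed in
tumours; planted probes are autosomal and never SNP-flagged so they
survive filtering. Per-sample noise is Gaussian (sd 0.05 by default) with
clipping to [0, 1]; missingness is injected completely at random.
Expression runs the regression model forward (`intercept + X beta +
noise`); survival times are exponential with hazard
`h0 * exp(riskScore)` under administrative uniform-horizon censoring
(the horizon is solved numerically so the expected censored fraction
matches the request); subtypes are balanced partitions of the tumours
with extra within-subtype shifts on the planted differential probes; the
PPI generator wires each planted hub to at least `hubDegreeMin` distinct
partners over a sparse background.

The generator deliberately omits: raw idat/intensity-level artefacts and
normalisation, probe-type (Infinium I/II) chemistry differences,
beta-value heteroscedasticity near 0/1, copy-number and tumour-purity
confounding, correlated missingness, batch effects, and competing risks.
Passing tests therefore demonstrate that the algorithms are correct and
well calibrated under a clean generative model matching their
assumptions — not that real cohort data are free of the confounders
above.

## Numerical choices and degenerate inputs

- Zero-variance probes: `p = 1`, never NaN.
- `M + U = 0`: missing beta, imputed downstream.
- Empty filter results warn instead of erroring so batch runs can report.
- `p = 0` in RS: floored at 1e-300.
- ES extremum ties: positive peak wins (documented, asserted against the
  oracle).
- Permutation p-values use add-one smoothing; they are never exactly 0.
- Rank-deficient regression designs: aliased probes dropped, logged.
- Maxstat ties: the more balanced split.
- All generators take an explicit integer seed and are bitwise
  reproducible; the pipeline derives fixed per-stage offsets from the
  master seed.

## Problem sizes used by the test and acceptance suites

The packaged checks run at desk scale, chosen so the whole suite
completes in about a minute while leaving the measured properties
comfortable margins: 2,000–5,000 probes with 30 tumour/30 normal samples
for differential power and null calibration; n = 100 samples for
regression coefficient recovery (tolerance 0.15); n = 500 for Cox
log-hazard recovery (tolerance 0.3); n = 300 for maxstat cutoff recovery
(tolerance 0.25); 1,000 permutations for the planted-set enrichment call;
500 resamples for 4-subtype consensus recovery; and a 1,500-probe
end-to-end determinism run. These sizes are the package's own choices and
are documented so users can scale them up when validating on their own
hardware.

## Known limitations

- Probe-wise differential calling only; no region/DMR calling.
- No penalised regression or mediation analysis for promoter effects.
- The naive maxstat p is biased by design (see above); use the
  permutation-corrected p for inference.
- Gene identifiers are uppercased symbols; no Entrez/Ensembl mapping.
- The three immune scores are the fixed-panel means; no deconvolution or
  ssGSEA-style scoring.

## A minimal run

```{r, eval = FALSE}
library(methylImmune)
res <- runPipeline("synthetic_run", pipelineConfig(seed = 1L))
readLines(file.path("synthetic_run", "manifest.txt"))
```
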
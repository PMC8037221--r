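---
title: "Benchmarking transcriptomic ICB-response biomarkers with icbBench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking transcriptomic ICB-response biomarkers with icbBench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icbBench)
```

## The problem

Immune checkpoint blockade (ICB) produces durable responses in only a
fraction of patients, and many transcriptomic biomarkers — from single
checkpoint genes to multi-gene enrichment scores — claim to predict that
fraction. Comparing them fairly requires holding everything else fixed:
the expression units, the responder definition, the discrimination
statistic, the survival workflow, and the way per-dataset results are
aggregated across cohorts of very different size. `icbBench` packages
that whole benchmark so each choice is explicit, configurable and tested.

The expected input is bulk expression as log2(TPM+1), genes as rows with
HGNC symbols, together with a per-sample clinical table (RECIST category,
OS/PFS times and event flags, dataset id, cancer type, therapy arm).
`alignCohort()` intersects the two sides into an `IcbCohort` (a
`SummarizedExperiment`), reporting any dropped samples.

## Scoring model, by family

All scorers consume log2(TPM+1) and are deterministic and
permutation-equivariant in samples.

* **Single gene / mean / weighted sum.** Arithmetic on the log scale. A
  geometric mean of TPMs (the original CYT definition) is exactly an
  arithmetic mean in log space, so no separate path is needed.
* **IMPRES (pairwise).** The count of ordered checkpoint-gene pairs with
  strictly greater expression of the first member; ties contribute 0.
  This makes the score an integer in [0, n_pairs] and invariant to any
  strictly increasing transform of a sample's expression values.
* **ssGSEA.** Per sample, genes are ranked by expression (descending,
  average ranks on ties) and a random walk steps down the list: in-set
  genes add `rank^alpha` normalized over the set, out-of-set genes
  subtract `1/(N - |set|)`. The enrichment score is the *sum* of the walk
  (integral form). Defaults: `alpha = 0.25`, no across-sample
  normalization. Both are configurable through `enrichmentParams()`
  because the literature varies on them; the defaults were fixed before
  any evaluation and are documented here as this package's convention.
* **TIS.** ssGSEA per T-cell subset, each subset z-scored across samples
  (population SD), then averaged over the nine subsets — hence each TIS
  column has mean zero across samples by construction.
* **GSVA-style (IPRES).** Each gene is first mapped to a
  relative-expression statistic across samples via a Gaussian-kernel
  cumulative density with Silverman's rule bandwidth
  (`0.9 * min(sd, IQR/1.34) * n^(-1/5)`); per sample the sets are scored
  by the rank walk, taking the maximum deviation from zero (signed), and
  the collection's scores are averaged. This is a desk-scale variant of
  the GSVA family: the cited tool is only named, not specified, in the
  benchmark literature, so the exact kernel and walk are declared here
  rather than inferred. Location shifts of a gene cancel in the kernel
  CDF, so the scores are invariant to them.
* **PC1 (Pan-F-TBRS).** First principal component of the z-scored member
  submatrix with samples as observations. PCA sign is arbitrary, so the
  score is oriented to correlate positively with the members' mean
  expression — a TGF-beta response score must increase with its genes.
* **Up/down (IRP).** Genes are centered across samples, then the
  per-sample mean over the up program minus the mean over the down
  program.
* **IPS scheme.** Gene-wise z-scores, averaged within weighted
  components, components averaged within the four categories (MHC, EC,
  SC, CP), category scores averaged, and the aggregate mapped affinely
  onto [0, 10] with clamping (0 at <= 0, 10 at >= 3). The map constants
  ship as config next to the gene tables.
* **MCP-counter.** Marker-gene arithmetic means on the log scale, one
  abundance row per population.
* **External (CIBERSORT.CD8, TIDE).** These biomarkers come from web
  tools; the package consumes them as precomputed per-sample columns and
  leaves the rows missing otherwise.

### Coverage rule

A biomarker whose member genes are not all measured is not evaluated:
its score row is NA and the coverage report records the measured
fraction. The default threshold is 1.0 (every gene required), reflecting
how panel platforms such as NanoString handle partially measured
signatures; RNA-seq users who tolerate small gaps can lower
`coverage_threshold`. Multi-subset signatures (TIS, IPRES) additionally
require each subset to pass the threshold.

### The signature registry

Gene lists, weights, pair lists and scheme tables ship as a YAML file,
not code, each entry annotated with its source publication. Several
published lists are printed only in their original papers; entries whose
transcription is a best-effort reconstruction carry
`note: reconstructed` and are meant to be replaced by corrected
transcriptions without touching package code. One deliberate modeling
choice lives here: the IS biomarker is published as a Bayesian
probability of an immune signature, and the package scores it as the
mean of its member genes. All downstream statistics used in the
benchmark (AUC, Wilcoxon, median splits) are rank-based, so any monotone
link between the surrogate and the published probability leaves them
unchanged; the surrogate is documented on the registry entry itself.

## Response labeling

Four RECIST-derived strategies share one rule for CR/PR (responder) and
PD (non-responder) and differ on SD: PD-strategy counts SD as response,
OR does not, OS gates SD on overall survival strictly greater than one
year, DCB on progression-free survival strictly greater than six months.
Boundary equality is a non-responder, exactly as the definitions are
phrased. SD patients lacking the needed time under OS/DCB are marked
unevaluable rather than dropped silently; samples without a RECIST
category are unevaluable everywhere but still scored. Calendar
conversions default to 365.25 and 182.625 days and are arguments, since
cohorts report time in different units.

## Evaluation statistics

* **Wilcoxon.** Exact null distribution when the combined sample is at
  most 20 and tie-free, otherwise the normal approximation with
  continuity and tie corrections. Reported p-values are floored at 1e-5
  (the raw value is kept alongside) so that vanishingly small p-values
  from large cohorts do not dominate summary displays.
* **Logistic regression.** The score is standardized to unit SD before
  the fit, making odds ratios per-SD and comparable across biomarkers
  with different native scales; Wald CIs and p-values are reported, and
  complete separation returns a flagged infinite-OR sentinel.
* **ROC/AUC.** The Mann–Whitney identity on direction-oriented scores
  (negative-direction biomarkers are negated first), with ties counted
  half. The raw, unoriented AUC is reported alongside.
* **Median split.** Strictly above the median is high, strictly below is
  low; median-tied samples join the smaller strict group. When the two
  strict groups tie in size the median samples join low — the published
  rule is silent on this sub-tie, and a fixed choice keeps every split
  deterministic. All-equal scores are a refused (degenerate) split.
* **Fisher / ORR.** The 2x2 of median-split group by objective response,
  two-sided by the point-probability convention, computed only on
  datasets with more than 20 evaluable patients.
* **Prediction score.** The sample-size-weighted mean of per-dataset
  AUCs, overall and per cancer-type/therapy stratum, with per-signature
  training datasets (a registry config field) excluded first.

## Survival workflow

Patients contributing more than one sample are excluded entirely before
survival analysis. The Kaplan–Meier and log-rank machinery is
implemented in the package (with the `survival` package serving as an
independent cross-check in the test suite): product-limit curves with
events preceding censorings at tied times, median survival as the
earliest time the curve reaches 0.5, landmark rates (default 24 weeks)
with Greenwood CIs computed on the log scale and clamped to [0, 1], and
the Mantel–Haenszel log-rank statistic referred to chi-square with one
degree of freedom. Biomarker survival uses exactly the same median-split
tie rule as the response evaluation, so the two analyses always split
patients identically.

## What the synthetic generator emulates — and what it does not

`simulateCohort()` emulates the *structure* of a multi-study ICB
benchmark: several datasets of a few dozen patients (defaults 41, 42,
50), a latent responder class (default share 0.5, which is what
PD-style labeling produces in pooled ICB cohorts), RECIST drawn
conditionally on that class so the objective response rate lands near
25–28%, planted mean shifts of d = 0.4 SD on a handful of signature
genes (oriented by each signature's documented direction, and sized so
the planted biomarkers score AUCs near 0.65–0.7, the range reported for
the better ICB biomarkers), and exponential OS/PFS with a hazard ratio
of 2 between classes under uniform censoring over three years. These
defaults are the package's fixed study conditions, chosen once and not
tuned against test outcomes.

Expression is Gaussian in log2(TPM+1) space truncated at zero, with
gene means uniform on [2, 6]. The generator does **not** model
co-expression networks, batch effects, count-level noise,
platform differences, or tumor purity — so passing recovery tests shows
the pipeline's statistics are correct and calibrated, not that any
biomarker will attain those AUCs on real tumors. The latent class is
recorded in the clinical table (`latent_class`) purely so recovery tests
can compare against ground truth.

Reproducibility: a single seed drives everything; per-dataset RNG
substreams are derived arithmetically from it, and an identical config
yields bitwise-identical cohorts and byte-identical written reports.

## Numerical choices and degenerate inputs

* Population (divisor n) SD everywhere genes are z-scored; zero-variance
  genes z-score to zero and are flagged.
* Duplicate gene symbols on input collapse by per-sample maximum (a
  declared convention — multi-transcript collapse is not standardized).
* Expression written to disk uses 17 significant digits so write/read
  round trips are exact.
* Walk-based scores break expression ties by average rank; the walk
  order among tied genes follows the stable sort, which monotone
  transforms preserve.
* Degenerate cases refuse loudly rather than guess: empty sample
  intersections, all-equal median splits, single-sample z-scores or
  GSVA, a gene set equal to the whole universe, constant scores in a
  logistic fit. No-event log-rank inputs return p = 1 with a warning.

## Problem sizes used by the test suite

The suite validates the statistics at sizes chosen to make the checks
sharp yet quick: 500 brute-force AUC instances at n <= 30; exact
rank-sum enumeration at 4-vs-4; null calibration with 2000 replicates at
n = 40 (Wilcoxon) and n = 100 (log-rank), expecting rejection within
[0.03, 0.07] at the 0.05 level; planted-effect recovery at n = 4000
with d = 1 on four genes against the analytic target
`pnorm(sqrt(2)) ~ 0.921` within 0.02; and 100 survival replicates at
n = 500 under a hazard ratio of 2, expecting detection in at least 90%.

## Limitations

* Reconstructed gene lists (see the registry notes) are placeholders for
  exact transcriptions of the original publications; scores built on
  them are structurally correct but not reference-identical.
* CIBERSORT deconvolution and the TIDE model are out of scope by design;
  those biomarkers only flow through when supplied as columns.
* No multivariable models, multiple-testing correction, or AUC
  confidence intervals: the benchmark reports unadjusted per-dataset
  statistics and aggregates by sample size, as the evaluation design it
  implements prescribes.
* Survival handles right censoring only — no competing risks, no
  interval censoring, no Cox models.
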
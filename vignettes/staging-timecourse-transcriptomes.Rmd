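---
title: "Staging a time-course transcriptome and calling stage-specific genes"
author: "stageTau authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging a time-course transcriptome and calling stage-specific genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressMessages(library(stageTau))
```

## The problem

Many brain insults — status epilepticus induced by kainic acid is the
motivating example — unfold over days: an acute phase in which the
transcriptome diverges rapidly from controls, and a later phase in which
it partially returns. A two-group time-course design (control vs insult,
several animals per group, a handful of time points spanning hours to
days) captures this, but most analyses collapse the time axis into
pairwise contrasts. `stageTau` instead treats the time course as a
trajectory: it locates the turning point of a marker pathway's activity,
splits the time points into a *progression* stage (up to and including
the peak) and a *remission* stage (after it), and then asks which genes
are expressed specifically in one stage — the molecular signature of each
phase of the disease.

The package is organized around a `StageExperiment` (a
`SummarizedExperiment` carrying the expression matrix, an explicit
linear/log2 scale flag, and the group/time/replicate design), with S4
result classes for the enrichment trajectory, the stage partition and the
cell-type scores.

## Staging: the ssGSEA trajectory

Neural excitability is tracked through the per-sample activity of a
marker pathway (in the motivating application, TGF-beta signaling). For a
gene set $S$ in a sample with $G$ genes, genes are ranked by expression
(descending, average ranks for ties, ties walked in gene-id order) and
the single-sample enrichment score is the integral form

$$ES = \sum_{i=1}^{G}\left[P^w_{in}(i) - P_{out}(i)\right],$$

where $P^w_{in}$ is the running sum of $r^\alpha$ over in-set genes
(normalized by the in-set total), $P_{out}$ the running fraction of
out-of-set genes, and $r$ the absolute rank with the top gene carrying
the largest value. Because only ranks enter, the score is invariant to
any monotone transform of a sample's values — normalization choices
upstream cannot flip a trajectory.

Two knobs are deliberately exposed rather than fixed:

* `alpha` (default **0.25**) — the rank-weighting exponent. The value is
  the common default of the single-sample variant of the statistic; the
  original description of the method names the algorithm but no
  parameters, so the default is a declared choice, not an inference.
* `normalize` (default **off**) — optional min–max scaling of scores
  across samples. Off by default because the per-time-point argmax that
  drives staging is unaffected by a monotone rescaling, and raw scores
  are easier to compare across runs.

The per-time-point score is the mean over **case** samples at that time
point; the peak is the argmax, with ties resolved to the earliest time
point (a documented, deterministic rule). `partitionStages()` places the
peak itself in the progression stage; a trajectory that is still rising
at the last time point yields an empty remission stage plus a warning
rather than an error, since that is a legitimate (if unstageable)
outcome.

## The Tau stage-specificity index

For each gene, per-stage representative expression $X_i$ over the $N$
stages is the mean of the **linear-scale** values across the case
replicates at stage $i$. Two points of care:

* **Linear scale.** The index divides expression values; ratios of
  log-transformed values have no such interpretation, so log2-stored
  matrices are back-transformed ($2^x$) before averaging. The mean is
  taken on the linear scale (mean of $2^x$, not $2^{\mathrm{mean}\,x}$).
* **Case samples only.** Stage specificity is a property of the disease
  trajectory, not of the contrast with controls; a
  `case_minus_control` variant is exposed for users who prefer the
  contrast view.

With $X_{max}$ and $X_{min}$ the row extremes,

$$\tau_{max} = \frac{\sum_{i=1}^{N}\left(1 - X_i/X_{max}\right)}{N-1},
\qquad
\tau_{min} = \frac{\sum_{i=1}^{N}\left(1 - X_{min}/X_i\right)}{N-1}.$$

Both lie in $[0,1]$: 0 for a uniformly expressed gene, 1 for a strictly
stage-confined one, and both are invariant to positive rescaling of a
gene's profile. $\tau_{max}$ flags genes specifically *high* in one
stage, $\tau_{min}$ genes specifically *low* in one stage; since both
patterns are biologically informative, a gene's specificity is
$\tau = \max(\tau_{max}, \tau_{min})$, its assigned stage is the stage of
the corresponding extreme, and its direction is recorded as up/down.
The combination rule is a package decision — the index's literature
computes both but does not prescribe how to merge them.

Profiles are floored at $\epsilon = 10^{-8}$ (logged per gene) so that
$\tau_{min}$'s ratio stays defined and $\tau_{max}=1$ remains exactly
representable for one-stage-only genes; excluding zero-containing genes
instead would silently discard exactly the most specific ones.

Calling uses the conventional inclusive threshold $\tau \ge 0.8$
(`callSpecificGenes`, sorted by descending $\tau$ then gene id).

```{r tau-example}
prof <- new("StageProfile",
            values = matrix(c(10, 5, 2, 1, 2), 1,
                            dimnames = list("gene1", c(1, 6, 24, 72, 240))),
            stages = c(1, 6, 24, 72, 240), flooredGenes = character())
as.data.frame(tauIndex(prof))
```

## Validating calls on an independent cohort

`validateStageGenes()` tests every called gene at every time point of a
validation cohort with a normality-gated two-group test: if both groups
pass a Shapiro–Wilk test at 0.05, a two-sided Welch t-test; otherwise a
Wilcoxon rank-sum test. A gene is *changed* when any raw per-time
p-value falls below 0.05 — mirroring the single-test convention of the
motivating analyses — and BH-corrected calls over each gene's time
points are emitted alongside for transparency.

Two statistical facts shape how this gate behaves at small $n$ and are
worth knowing before designing a cohort:

* the two-sided Wilcoxon test at 3 vs 3 cannot produce $p < 0.1$, so any
  replicate that falls to the nonparametric branch at $n = 3$ is
  untestable at $\alpha = 0.05$;
* the gate sends roughly 10% of perfectly normal 3 vs 3 comparisons to
  that branch (5% per group), capping the gated test's power near 0.9
  regardless of effect size.

From $n = 4$ per group upward both branches can reject at 0.05, and at
$n = 5$ the gated test detects a 5-SD shift essentially always. For this
reason the package's immune-trajectory experiments (below) use 5
replicates per group even though the discovery design defaults to 3.

## Enrichment machinery

**Preranked GSEA** (`gseaPreranked`) uses the classic running-sum
statistic (in-set increments proportional to $|m|^{weight}$, uniform
out-of-set decrements, ES = maximum deviation from zero) with a
**gene-set permutation** null: `nPerm` (default 1000) random same-size
sets drawn from the ranked universe. The normalized score is
$NES = ES / \mathrm{mean}(|ES_{null}|)$ over same-sign nulls, and
$p = (b+1)/(n_{same-sign}+1)$, never exactly zero. A consequence of the
same-sign convention: for a strongly positive observed ES roughly half
the nulls are negative, so the attainable p floor at 1000 permutations is
about $1/500$, not $1/1000$. Under the global null the p-values are
calibrated (the test suite checks the rejection fraction and
uniformity).

**Over-representation** (`oraTest`) is the one-sided upper-tail
hypergeometric $P(X \ge k)$ per set with BH correction across sets; the
raw $p < 0.05$ flag is kept alongside because the motivating analyses
threshold on raw p.

## Heterogeneity

`pcaTopVariable` ranks genes by standard deviation across all samples
(ties by gene id), keeps the top 500 by default, and performs PCA on
centered but **unscaled** gene vectors — genes were already selected *by*
SD, so their raw dispersion structure is the signal. Component signs are
fixed by flipping any loading vector whose sum is negative, making scores
reproducible across platforms. `groupDistanceByTime` reports, per time
point, the mean Euclidean distance over all control x case sample pairs
computed on **all** genes (mean over cross-group pairs is the declared
aggregation; a per-sample-pair view would need matched samples the
design does not guarantee), and `groupCorrelationByTime` the Pearson
correlation between the group-mean profiles.

## Immune context

The immune arm deliberately implements *generic* algorithms against
user-supplied signatures rather than replicating any fixed-signature
tool: the immune score is the ssGSEA score of an immune gene list;
cell-type abundance comes either from marker-set ssGSEA scores
(`scoreCellTypes`, no cross-type normalization — scores compare samples
within a type, not types within a sample) or from non-negative
least-squares deconvolution (`deconvolve`), which renormalizes the NNLS
coefficients to proportions and reports the per-sample residual norm in
place of a permutation credibility p-value. Gene–cell-type association
uses Spearman's rho (average ranks) with a two-sided t-approximation p
(an exact small-sample option exists for $n \le 10$ without ties), and
genes are grouped by average-linkage hierarchical clustering on
$1 - \mathrm{cor}$ of their rho profiles, cut by default into as many
clusters as there are distinct stages among the genes.

## The synthetic study

`simulateTimecourse()` is first-class, tested code: it generates the
study conditions every recovery test runs against.

* **Design**: five time points (1, 6, 24, 72, 240 h), 3 replicates per
  group per time point — the sampling scheme of the motivating
  kainic-acid study.
* **Baselines**: per-gene log2 baseline $\mathcal{N}(6, 1.5)$, replicate
  noise $\mathcal{N}(0, 0.3)$ — typical microarray-like dispersion.
* **Stage-specific genes**: 10 up and 10 down per stage at log2 fold
  change 3, applied to case samples at the planted stage only. Effects
  are additive on the log2 scale (multiplicative on linear), which keeps
  the back-transformed Tau inputs positive. Down-specific genes are
  planted because $\tau_{min}$ exists precisely to find specifically-low
  expression.
* **Pathway**: 50 genes (a typical curated-pathway size, and small
  enough to keep the default matrix mostly null) sharing a trajectory
  that is a symmetric triangle in log10-time around the planted peak
  (default 24 h, amplitude 1.5), the simplest unimodal shape that rises
  and then falls across logarithmically spaced time points.
* **Immune signature**: optionally, genes whose activation is zero
  before an onset time point and rises linearly in log-time afterwards —
  the "no early difference, growing late difference" pattern.
* **Mixtures**: `simulateMixtures()` builds linear-scale bulk profiles
  as signature x proportions under multiplicative log-normal noise, with
  `simulateSignature()` providing a well-conditioned marker-block
  reference.

Everything is deterministic under the configured seed.

What the generator does **not** emulate: probe-level artifacts,
background correction, batch effects, gene–gene correlation beyond the
planted structure, heavy-tailed noise, or platform-specific intensity
distributions. Recovery tests passing on this generator therefore
demonstrate that the algorithms are implemented correctly and behave as
designed under realistic dispersion — not that any particular real
dataset will yield the same gene counts.

## Numerical and design choices

* Ties: average ranks everywhere a rank is taken; walk/sort order on
  ties is stable by gene id, making every score bit-reproducible.
* Peak ties resolve to the earliest time point.
* Duplicate gene ids on load are collapsed by their mean (logged);
  rows that are entirely missing are dropped; any other missing cell is
  an error rather than an imputation.
* The pipeline derives per-stage seeds from one master seed by fixed
  offsets, so adding a stage never shifts another stage's stream, and
  re-running a config reproduces byte-identical tables.
* Problem sizes in the test-suite experiments (a 2000-gene discovery
  run for recovery; 800-gene runs per planted peak; 400-gene,
  5-replicate cohorts for the immune pattern; 500 null GSEA runs at 1000
  permutations; 50 mixtures for deconvolution) were chosen as the
  smallest designs at which the statistical properties under test are
  stable.

## Limitations

* The Tau index needs non-negative linear expression; strongly negative
  log-ratio data have no meaningful back-transform.
* With two groups of 3 the gated test's nonparametric branch is
  powerless at $\alpha = 0.05$ (see above); validation cohorts should
  provide at least 4 replicates per group.
* NNLS deconvolution assumes the signature spans the mixture; a missing
  cell type inflates the residual norm rather than failing loudly.
* The stage partition assumes a unimodal trajectory; multimodal pathway
  activity will be split at the global maximum only.
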
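# stageTau

Staging a two-group time-course transcriptome and calling
stage-specifically expressed genes.

## What it does

Insult-driven brain disease (the motivating system is kainic-acid-induced
status epilepticus in the rat, sampled at 1, 6, 24, 72 and 240 h) unfolds
as a trajectory: the transcriptome diverges from controls, peaks, and
partially recovers. `stageTau`:

1. tracks a marker pathway's activity per sample with **ssGSEA** and
   splits the time course at the trajectory peak into a **progression**
   stage (time points up to and including the peak) and a **remission**
   stage (after it);
2. computes the **Tau specificity index** per gene over the per-stage
   case means X<sub>i</sub> (linear scale, N stages):

   τ<sub>max</sub> = Σ<sub>i</sub> (1 − X<sub>i</sub>/X<sub>max</sub>) / (N−1),  
   τ<sub>min</sub> = Σ<sub>i</sub> (1 − X<sub>min</sub>/X<sub>i</sub>) / (N−1),

   both in [0, 1] (0 = uniform expression, 1 = strictly stage-confined);
   genes with τ = max(τ<sub>max</sub>, τ<sub>min</sub>) ≥ 0.8 are called
   stage-specific, each with an assigned stage and an up/down direction;
3. **validates** the calls on an independent cohort with a
   Shapiro–Wilk-gated t/Wilcoxon test per gene and time point;
4. profiles the stages with preranked **GSEA** (gene-set permutation
   null), hypergeometric **over-representation**, sample
   **heterogeneity** summaries (PCA on the most-variable genes,
   between-group distance and correlation per time point), and an
   **immune arm** (signature ssGSEA scores with per-time group tests,
   marker-based cell-type scores, non-negative least-squares
   deconvolution, gene-by-cell-type Spearman correlation with
   clustering);
5. ships a **synthetic-data generator** with planted ground truth
   (stage-specific genes, a pathway peaking at a chosen time point, an
   immune signature rising from an onset, cell-type mixtures) so every
   stage of the pipeline has a recovery test with no downloads.

The data container is a `StageExperiment` (a `SummarizedExperiment` with
an explicit linear/log2 scale flag and the group/time/replicate design);
inputs are plain TSV matrices, TSV sample metadata and Broad-dialect GMT
gene sets.

## Worked example

The bundled demo generates the default synthetic study (2000 genes,
5 time points, 3 replicates/group, a 50-gene pathway peaking at 24 h, an
immune signature rising from 24 h, plus a validation cohort and a
mixture/signature bundle), writes all inputs, and runs the pipeline end
to end:

```r
library(stageTau)
res <- runDemo(seed = 1, outDir = "demo_out")
```

prints

```
== stageTau demo summary ==
pathway peak: 24 h
progression stages: 1, 6, 24 h
remission stages: 72, 240 h
stage-specific genes (tau >= 0.8 ): 100
validation [progression]: 60/60 genes changed
validation [remission]: 40/40 genes changed
immune score significant at: 24, 72, 240 h
```

Reading the numbers: the ssGSEA trajectory of the planted pathway peaks
at 24 h, so the partition reproduces the 1–24 h vs 72–240 h split; all
100 planted stage-specific genes (10 up + 10 down at each of 5 stages)
are recovered at τ ≥ 0.8; every recovered gene shows a significant
control-vs-case change somewhere in the validation cohort (which plants
the same effects); and the immune score separates the groups exactly
from its 24 h onset onward, not at 1 h or 6 h. `demo_out/results/`
contains the full tables (`tau_index.tsv`, `specific_genes.tsv`,
`pathway_trajectory.tsv`, `stage_partition.tsv`, `validation_*.tsv`,
`immune_*.tsv`, `deconvolution.tsv`, `ora.tsv`, `gsea_peak.tsv`) and a
`manifest.json` with parameters, seed and per-stage timings.

A thin CLI wrapper lives at `inst/scripts/stagetau.R`
(`Rscript stagetau.R demo --seed 1`, or `run --config cfg.yaml` with a
YAML config matching `pipelineConfig()`).

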
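---
title: "Grouping, scoring and modeling across three omics layers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grouping, scoring and modeling across three omics layers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trimint)
library(dplyr)
```

## The problem and the model

MicroRNAs repress their target mRNAs post-transcriptionally, and promoter
CpG methylation silences transcription; when a miRNA and a CpG probe track
each other across samples, the genes co-varying with both are candidates for
a shared regulatory module. trimint looks for exactly these modules in three
matched feature-by-sample matrices — miRNA expression $A$, CpG methylation
$B$, mRNA expression $C$ — measured on the same samples with a two-class
phenotype, and asks whether the modules it finds can classify the phenotype.

The pipeline has four stages applied per train/test split:

1. **Pairing (P).** All $|A| \times |B|$ feature pairs are scanned; a pair
   $(a_i, b_j)$ is retained when $|\mathrm{cor}(a_i, b_j)| > \alpha$
   (strict) with a two-sided correlation p-value below `pair_p_max`. The
   p-value uses the exact t transform $t = r\sqrt{(n-2)/(1-r^2)}$ on $n - 2$
   degrees of freedom.
2. **Grouping (G).** For each retained pair, every gene $c_k$ with
   $|\mathrm{cor}(a_i, c_k)| > \beta$ and $|\mathrm{cor}(c_k, b_j)| > \beta$
   joins the group named `mirna_cpg`. Pairs with no qualifying gene are
   dropped.
3. **Scoring (S).** Each group's gene submatrix of the training samples is
   scored by stratified Monte Carlo cross-validation of a random-forest
   classifier; the score is the mean over inner iterations of a weighted
   metric combination (accuracy by default). Groups are ranked by score.
4. **Modeling (M).** For $k = 1 \dots K$ the union of the $k$ best groups'
   genes feeds a fresh random forest trained on the training samples and
   evaluated on the held-out samples, giving the cumulative performance
   table (accuracy, sensitivity, specificity, Mann–Whitney AUC).

The outer loop repeats stages over `n_outer_splits` stratified 90/10
train/test splits, then aggregates: which groups recur (frequency), how
well and how high they score on average, which miRNAs/CpGs/genes carry
them, best-rank co-occurrence matrices across splits, and a shared-gene
Jaccard similarity between groups.

Before any of this, methylation input passes standard array QC: probes with
more than `max_missing_fraction` missing values are removed (survivors are
mean-imputed per probe), probes with interquartile range at or below
`min_iqr` are removed, and user-supplied blocklists (sex-chromosome, SNP,
cross-reactive probes) are excluded. All three layers then pass a
per-feature two-class Welch t-test filter at `ttest_p_max`.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.6 | pair correlation threshold, strict on $\lvert r\rvert$ |
| `beta` | `alpha` | group (gene) correlation threshold |
| `pair_p_max`, `ttest_p_max` | 0.05 | p-value gates for pairing and the differential filter |
| `n_outer_splits` | 100 | outer Monte Carlo splits |
| `test_fraction` | 0.1 | held-out fraction per split |
| `inner_cv_iterations`, `inner_test_fraction` | 5, 0.1 | inner scoring CV, mirroring the outer 90/10 regime |
| `top_k_groups` | 10 | cumulative models built for $k = 1..10$ |
| `min_group_frequency` | 5 | groups seen in $\le 5$ splits are excluded from the significance tables |
| `rf_trees` | 100 | trees per forest, $\sqrt{p}$ candidate features per node |
| `leakage_mode` | `"global"` | where discovery sees its samples (below) |

The defaults for `alpha`, the p-value gates, the 90/10 × 100 split regime,
the top-10 cumulative models and the frequency floor of 5 are the
recommended operating point of the method; `beta` has no canonical
recommendation, so it defaults to `alpha`.

## Design choices where the method is genuinely open

**Absolute versus signed `beta`.** The grouping condition is applied to
$|r|$ by default, consistent with the pairing stage and with the biology —
miRNA repression and methylation silencing make *negative* associations
meaningful. `use_abs_beta = FALSE` restores the literal signed reading
$r > \beta$ for users who want only positive co-expression.

**Information leakage.** With `leakage_mode = "global"` the t-test filter,
pairing and grouping see all samples, and only scoring/modeling respect the
train/test boundary — this mirrors the method's published order of
operations, but the held-out metrics are then optimistically biased because
feature discovery has seen the test samples. `"train_only"` repeats the
whole discovery inside each split on training samples only; it is slower
and produces split-to-split variation in the detected groups (which is what
makes the frequency statistics informative), and is the recommended setting
when unbiased test metrics matter.

**Welch by default.** The differential filter uses the unequal-variance
t-test — the robust default for omics group comparisons; a pooled-variance
variant is available via `var_equal`. Degenerate features (zero variance in
both classes) get $p = 1$ when the class means agree, $p = 0$ when they
differ.

**Shared inner partitions.** Within one split, every group is scored on the
same inner Monte Carlo partitions and with the same forest seeds. Scores
are therefore directly comparable, and two groups with identical gene sets
score identically; ties break toward larger groups (more informative for
the cumulative models), then lexicographically.

**Deterministic everything.** One master seed drives the run; split $i$
uses `seed + i`, and inner splits and forests derive further streams from
it. Pair lists sort by $|r|$ descending then IDs, genes within a group by
the weaker of their two link correlations, samples by lexicographic ID.
Two runs from the same inputs and seed are byte-identical on disk (numeric
output is rendered at 6 significant digits).

**Aggregation conventions.** "Detected in a split" means the group appeared
in the split's scored list at all; `count_top_k_only = TRUE` restricts
counting to the split's top $k$. Feature-level average score/rank are
occurrence-weighted over (split, group) pairs. In the rank matrices, an
absence is kept missing in the exported files but imputed as one-worse-than
worst for the Euclidean average-linkage clustering of the split columns.
The across-splits performance summary reports both the largest union size
observed at $k$ (`n_unique_genes`) and its mean over splits
(`average_gene_n`); the aggregation of these two columns over splits is an
interpretation this package fixes explicitly, since only their per-split
definition is canonical.

## What the simulator emulates — and what it does not

`simulate_triomics()` draws, for each planted module $m$ and sample $s$
with class $y_s$, a latent factor
$z_{ms} = \mathrm{effect\_size}\cdot[y_s = \mathrm{case}] + \varepsilon$,
$\varepsilon \sim N(0,1)$, and gives the module's miRNA, CpG and each of
its genes the value
$\pm(\lambda z_{ms} + \sqrt{1-\lambda^2}\,\eta)$ with loading $\lambda$ and
feature noise $\eta \sim N(0, \mathrm{noise\_sd}^2)$; the sign is drawn
independently per CpG/gene so negative associations occur. Background
features are independent standard normals. Two features of one module then
have population correlation $\lambda^2$ when `effect_size = 0`
(`expected_pair_correlation()`), rising with the shared class effect — the
default $\lambda = 0.8$ puts planted pairs at $r \approx 0.64$–$0.78$,
safely above $\alpha = 0.6$, which is what makes threshold tests
principled rather than tuned.

The default generator settings — 60 samples per class, 3 modules of 5
genes, 200 background features per layer, loading 0.8, effect size 2 —
are the fixed study conditions for the package's calibration experiments.
The simulator deliberately does **not** mimic real-data features:
methylation beta-value marginals (a logistic squash is available via
`cpg_bounded`, off by default so correlations stay exactly analyzable),
count overdispersion, library-size or batch effects, correlated background,
or many-to-many miRNA–target maps. Passing the planted-recovery and null
calibration tests therefore demonstrates correctness of the machinery under
a favourable, well-specified signal model — not expected performance on
TCGA-scale data.

## Numerical conventions and degenerate inputs

* Quantiles for the IQR filter use linear interpolation between order
  statistics (R type 7); retention near the threshold depends on this
  choice, hence it is fixed and documented.
* Correlations are computed by standardise-then-crossproduct and clamped to
  $[-1, 1]$; $|r| = 1$ maps to $p = 0$. Zero-variance features are skipped
  with a logged count rather than producing NaNs.
* AUC is the Mann–Whitney rank statistic with ties counted one half; the
  positive-class score is the forest's vote fraction. Single-class truth
  yields `NA` AUC.
* Stratified splits draw per class $\max(1, \mathrm{round}(f\,n))$ test
  samples, capped so training keeps every class; candidates are visited in
  sample-ID order, making the drawn sample *sets* independent of input
  column order. An inner split that would lose a class is redrawn from a
  derived seed (at most 10 attempts).
* Zero detected pairs or groups is a valid outcome: the split completes
  with empty tables and a warning, matching runs where weak thresholds find
  nothing.

## Problem sizes used in the shipped experiments

The calibration experiments run at the default study conditions: the
planted-recovery experiment uses 50 independent fixtures with 10 outer
splits each, the null calibration 20 fixtures with zero effect size and
three splits each (pooling 12,000 background features for the size of the
t-test), and the acceptance script's flagship run performs the full 100
outer splits on one default fixture. Null calibration disables the
differential filter (`ttest_p_max = 1`): under a zero class effect the
planted features survive that filter only at its nominal 5% rate, so with
the filter active almost no run would form a group and there would be
nothing to measure; with it disabled, pair formation is driven by the
loading-only correlation and the chance-level behaviour of the downstream
classifier is actually exercised.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_triomics(n_samples_per_class = 30, n_background = 50, seed = 3)
cfg <- trimint_config(n_outer_splits = 10, min_group_frequency = 0, seed = 3)
run <- trimint_run(sim$mirna, sim$cpg, sim$mrna, sim$labels, cfg,
                   preprocess = FALSE)
tidy(run, "groups")
glance(run)
plot_performance(run)
plot_rank_heatmap(run$rank_matrices$group)
write_trimint_outputs(run, "outdir")
```

## Known limitations

* The exhaustive pair scan is $O(|A|\,|B|)$ in memory for the correlation
  matrix; at array scale (hundreds of thousands of CpGs) it should be run
  after the QC and differential filters, which is the intended order.
* Only the random forest ships as classifier; the `classifier_spec()`
  interface is the extension point.
* `"global"` leakage mode reproduces the published workflow but its test
  metrics must not be read as unbiased generalisation estimates.
* Group names assume `_` does not occur inside miRNA IDs when parsed back
  from files; in-memory tables carry the IDs separately.
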
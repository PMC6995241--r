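---
title: "Cross-study marker discovery and neural-network sample classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-study marker discovery and neural-network sample classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the method

Bulk expression studies of the same disease — here the motivating case is
pancreatic ductal adenocarcinoma (PDAC) versus normal pancreas — rarely
agree gene-by-gene, because platforms, labs and cohorts differ. A robust
signature can nevertheless be obtained by demanding *replication*: run a
differential-expression analysis in every study separately and keep only
the genes that are called, in the same direction, in all of them (the
core-gene set). `coremarker` implements that meta-analysis, the
cross-platform rescaling needed to pool samples, an AUC-plus-protein-
evidence marker ranking, and a small feed-forward neural network that
classifies a sample as normal or tumor from the selected markers alone.

The stages, each an exported function and a CLI subcommand:

1. **Per-study DEG analysis** (`deg_analysis`). Genes with no expression
   variation are removed; multiple probes per gene are collapsed to the
   probe with the maximum mean expression; a two-group t-statistic is
   computed per gene; p-values are Benjamini–Hochberg adjusted; a gene is
   called when `|log2FC| >= 1` and adjusted `p <= 0.05`.
2. **Core-gene intersection** (`intersect_core`). Calls shared,
   direction-consistently, by all studies.
3. **Standardize and merge** (`standardize_rescale`, `merge_studies`).
   Per gene within each study, `X' = (X - mean(X)) / sd(X)` followed by a
   min-max rescale to `[0, 1]`, so studies from different platforms live on
   a common scale before pooling.
4. **Marker selection** (`auc_table`, `ihc_confirm`, `select_markers`).
   Core genes ranked by the per-gene ROC AUC on the merged matrix; only
   genes whose protein expression is confirmed by immunohistochemistry
   (at least 75% of staining images high or medium) are eligible; the top
   five by AUC become the classifier inputs.
5. **Classifier** (`architecture_search`, `train_mlp`, `predict`). A
   feed-forward network with five inputs, one or two relu hidden layers of
   2–10 nodes, and a two-node softmax output. All 90 architectures in that
   grid are trained 30 times each; architectures are ranked by mean
   training accuracy and the single best-trained run of the winner is kept.
6. **Evaluation and QC** (`confusion`, `sens_spec`,
   `classification_report`, `pca_scores`, `hcluster_two`). Confusion
   matrix, sensitivity/specificity, per-class precision/recall/F1 with a
   support-weighted average, PCA scores, and a two-group hierarchical
   clustering with per-class agreement ratios.

## Statistical model and assumptions

**Two-group statistics.** The default per-gene statistic is an
empirical-Bayes *moderated t*: with pooled per-gene variance $s_g^2$ on
$d_g = n - 2$ degrees of freedom, the shrunken variance is

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},$$

where the prior $(d_0, s_0^2)$ is fitted by moment-matching on
$\log s_g^2$: writing $e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$, the
excess of $\mathrm{Var}(e)$ over $\psi'(d_g/2)$ identifies $\psi'(d_0/2)$,
inverted by Newton's method on the trigamma function. The t-statistic is
referred to $d_0 + d_g$ degrees of freedom (capped at the pooled residual
degrees of freedom across genes). If the excess variance is non-positive
the prior is infinitely informative and $\tilde s_g^2$ is the mean sample
variance — in that degenerate case moderated and pooled t coincide. A
Welch unequal-variance t (Satterthwaite df) is available via
`deg_method = "welch"`. Both assume approximately Gaussian log2
expression within groups, the standard post-normalization microarray
assumption.

**BH adjustment.** Step-up on the sorted scale,
$\tilde p_{(i)} = \min(1, \min_{j \ge i} p_{(j)} m / j)$. Exact zeros are
floored at the smallest positive double first so the sort order stays
well defined.

**AUC.** The per-gene AUC is the rank statistic
$P(X_{tumor} > X_{normal}) + \tfrac12 P(\text{tie})$ computed from
midranks, which equals the trapezoidal area under the empirical ROC
curve. It is *directed* (tumor-high positive); a direction-agnostic
`max(AUC, 1 - AUC)` folding exists behind `fold_auc` for exploratory use
but is off by default, since the intended markers are upregulated.

**Network and training.** Weights initialize i.i.d. uniform on
$[-1, 1]$ and every bias at 1; hidden activations are relu, the output is
a numerically stabilized softmax. Training minimizes mean categorical
cross-entropy by plain mini-batch SGD: learning rate 0.05, 100 epochs,
batch size 32, samples reshuffled every epoch. Loss, optimizer and batch
size are the conventional defaults of small dense classifiers; all are
exposed in `run_config()`.

## Tunable parameters

| parameter | default | units / range | why |
|---|---|---|---|
| `lfc_threshold` | 1.0 | log2 units | a two-fold change, the conventional biological-relevance gate |
| `fdr_threshold` | 0.05 | proportion | BH-adjusted significance |
| `variance_epsilon` | 0 | log2² units | removes exactly the no-variation genes |
| `core_min_fraction` | 1.0 | proportion of studies | core = shared by *all* studies |
| `ihc_threshold` | 0.75 | proportion of images | protein evidence rule (≥, so an exact 75% passes) |
| `n_markers` | 5 | count | one network input per marker |
| `hidden_node_range` | 2..10 | nodes | grid bounds |
| `max_hidden_layers` | 2 | layers | grid depth; 9 + 81 = 90 architectures |
| `repetitions` | 30 | count | trainings per architecture |
| `learning_rate` | 0.05 | — | SGD step |
| `epochs` | 100 | count | fixed-length training, no early stopping |
| `batch_size` | 32 | samples | mini-batch SGD |
| `split_fraction` | 0.2 | proportion | internal stratified test split |

## Design choices where the design was open

- **Standardization scope.** Default is per gene *within each study*,
  then merge: the rescale exists to bring different platforms onto one
  range, and doing it per study removes per-study location/scale shifts by
  construction. A `rescale_scope = "merged"` variant (one pass over the
  pooled matrix) is selectable for sensitivity analyses.
- **Direction consistency** is required for core membership by default: a
  signature gene whose sign flips between studies is not a usable marker.
  `require_direction = FALSE` relaxes this.
- **DEG rule reads the fold-change gate as |log2FC|** with the sign giving
  the direction; a one-sided reading would make downregulated calls
  impossible, contradicting the existence of a downregulated core gene.
- **AUC scope** is the merged discovery matrix — the same input the
  classifier trains on — rather than per-study AUCs averaged.
- **Best-trained network** is chosen by training accuracy within the
  architecture that wins on *mean* training accuracy over its 30 runs;
  the internal stratified 80/20 test split and any validation studies are
  never consulted during selection.
- **Seed discipline.** Every random draw derives from one integer seed.
  Run $r$ of architecture $a$ uses
  `seed_hash(seed, a, r) = ((seed mod M) 31 + a) 31 + r mod M`,
  $M = 2^{31}-1$ — injective over the grid, so any single run can be
  reproduced in isolation. The compiled training loop is RNG-free; weight
  draws and epoch shuffles come from R's RNG and are passed down.
- **Gene identifiers are opaque strings.** Harmonizing symbols versus
  Entrez ids across platforms is left to the caller; the intersection is
  exact string matching.
- **Serialization** is a flat, human-diffable `key: value` text dialect
  (row-major weight lists, 17 significant digits) so models and configs
  round-trip at full precision without a binary dependency.

## Numerical conventions, tie-breaks, degenerate inputs

- Probe collapse: representative probe = maximum mean expression; ties go
  to the lexicographically smallest probe id. Unmapped probes drop with a
  warning.
- Zero-variance gene in `standardize_rescale`: all values become 0.5
  (the midpoint carries no class information) with a warning.
- Welch t with zero within-group variance in both groups: p is 0 when the
  means differ and 1 otherwise, flagged by a warning; the moderated prior
  handles the same case smoothly (variances are floored at
  `1e-5 * median` before the prior fit).
- Marker ties at the k-th AUC go to the smaller gene id; architecture-
  search ties go to the earlier architecture and repetition; exact
  probability ties in `predict` go to "normal".
- Softmax is computed after subtracting the row maximum; training aborts
  with the epoch number if the loss ever becomes non-finite.
- Cluster-to-label mapping ties assign cluster 1 to "normal"; PCA
  component signs are fixed by making the largest-magnitude loading
  positive.

## What the synthetic generator emulates — and what it does not

`generate_collection()` plants ground truth in a collection of studies:
each cell is

```
baseline_mean + study_shift + gene_offset
  + direction * effect_size * is_tumor + N(0, noise_sd)
```

with the signed effect applied to a core set shared by every study (39 up,
1 down by default) and to a disjoint study-specific DEG set per study.
Defaults — 10 studies, 2000 genes, 40 tumor / 20 normal samples per study,
effect 2.0, noise 0.7, study shifts of sd 0.5 on the log2 scale — emulate
the shape of a ten-study microarray compendium with roughly 2:1
tumor:normal imbalance. Per-gene baseline offsets (sd 1.0, a value chosen
once as a realistic between-gene spread) are drawn a single time and
shared across studies so a gene is comparable between studies; the
additive per-study shift is what motivates the per-study standardization.
`generate_ihc_counts()` fabricates a staining-category count table in
which a chosen fraction of genes passes the ≥75% high+medium rule.

What it deliberately does *not* model: probe-level effects beyond a
simple duplicated-row mode (`probe_level_study`), missing values,
correlated genes, batch structure within a study, platform-specific
dynamic-range compression, or class-dependent variance. Passing tests on
this generator therefore demonstrates that the pipeline's logic is
correct and recovers planted truth under idealized noise — not that any
particular accuracy will transfer to real cohorts, where effect sizes are
smaller and correlation structure matters.

## Problem sizes used by the test suite

Unit and property tests run on small fixtures (tens of genes, a handful
of samples) built in code. The end-to-end check uses the generator
defaults — twelve studies of 2000 genes × 60 samples, ten for discovery
and a held-out pair for validation — and runs the full 90-architecture ×
30-repetition search for five pipeline seeds, requiring ≥95% recovery of
the planted core with zero study-specific contaminants, all five selected
markers inside the planted core, and ≥85% validation accuracy in at least
four of the five seeds. `scripts/acceptance.R` performs one such run for
a supplied seed and writes the resulting quantities as JSON.

## Known limitations

- The moderated-t implementation covers the two-group design only — no
  covariates, contrasts, paired designs or array weights.
- No batch correction beyond per-study standardization; strong
  confounding between study and class would bias the core set.
- The classifier has no regularization or early stopping; with five
  inputs and ≤ 20 hidden nodes overfitting pressure is mild, and the
  repeated-training protocol absorbs unlucky initializations, but the
  training-accuracy selection criterion can still favor memorization on
  small cohorts.
- AUC confidence intervals (e.g. DeLong) are out of scope; marker ranking
  uses point estimates.

```{r example}
library(coremarker)

params <- simulation_params(n_studies = 12, seed = 1)
coll <- generate_collection(params)
cfg <- run_config(seed = 1)

ihc <- generate_ihc_counts(coll$truth$core$gene, confirm_fraction = 0.35,
                           images_per_gene = 12, seed = 2)
report <- run_pipeline(cfg, coll$studies[1:10],
                       validation_paths = coll$studies[11:12],
                       ihc_path = ihc, out_dir = "run", verbose = TRUE)
print(report)
```
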
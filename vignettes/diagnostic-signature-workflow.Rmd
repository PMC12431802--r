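---
title: "Methods: from differential expression to a gene-score neural classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from differential expression to a gene-score neural classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigscoreann)
```

## The problem and the model

`sigscoreann` builds a diagnostic classifier for a two-group transcriptomic
study — here motivated by vitiligo, comparing lesional (case) against
nonlesional (control) skin on log2 microarray intensities — through four
chained stages:

1. **Differential expression.** For each gene, the effect is the log2 fold
   change `logFC = mean(case) − mean(control)`, tested with a two-sample
   t-statistic. The default is an empirical-Bayes *moderated* t: per-gene
   pooled residual variances $s_g^2$ (df $d_g = n - 2$) are shrunk toward a
   prior $s_0^2$ with prior df $d_0$,
   $\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$, and the statistic
   $\tilde t_g = \mathrm{logFC}_g / \sqrt{\tilde s_g^2 (1/n_1 + 1/n_2)}$ is
   referred to a t distribution on $d_0 + d_g$ df. $(d_0, s_0^2)$ are
   estimated by the method of moments on $\log s_g^2$ with trigamma
   inversion — the standard empirical-Bayes recipe for stabilizing
   small-sample microarray variances; the test suite verifies the
   implementation against limma. Classical pooled and Welch statistics are
   available as reference methods. Genes are declared differentially
   expressed when (BH-adjusted, by default) p < 0.05 **and** |logFC| > 1,
   both inequalities strict.

2. **Random-forest signature selection.** A 500-tree classification forest
   is grown on the continuous expression of the DEGs (bootstrap samples,
   `mtry = floor(sqrt(p))`, unlimited depth — the de-facto classification
   defaults). The out-of-bag (OOB) error curve over tree counts 1..500,
   overall and per class, locates the error-minimizing tree count
   (diagnostic only; the full forest is kept for importance). Genes are
   ranked by mean decrease in Gini impurity (permutation importance by
   option) and the top 30 form the signature.

3. **Binary gene scores.** Each signature gene is dichotomized at its
   median: an upregulated gene scores 1 in samples where its expression
   strictly exceeds its median, a downregulated gene scores 1 strictly
   below, and 0 otherwise (ties at the median score 0 in both directions).
   The source description of this rule is garbled ("the number of
   upregulated genes was higher than the median"); the only reading that
   yields the per-gene, per-sample 0/1 matrix the downstream classifier
   consumes is the one implemented here, and it is stated explicitly in
   `?score_matrix`. The score depends only on a gene's rank relative to its
   median, so it is invariant to any strictly increasing transform of that
   gene — a deliberately coarse, normalization-robust representation.

4. **Feed-forward network.** A single-hidden-layer perceptron — k = 30
   inputs (the gene scores), 5 logistic hidden units, one logistic output
   giving the case probability — is trained by full-batch gradient descent
   on binary cross-entropy. For a two-class problem the single sigmoid
   output is equivalent to the two-softmax-node layout often drawn for such
   networks, and it yields the ROC score directly.

Evaluation uses in-package ROC/AUC: thresholds at unique score values with
ties grouped (all-tied scores give exactly the diagonal), trapezoidal area,
which the tests prove equal to the Mann–Whitney pair-ordering probability.
Case is always the positive class and the curve is never auto-flipped.

## Tunable parameters

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `p_threshold`, `lfc_threshold` | 0.05, 1.0 | DEG cut-offs on (adjusted) p and \|logFC\| (log2 units); strict inequalities. |
| `use_adjusted` | `TRUE` | Filter on BH-adjusted p. The workflow's two stated cut-offs ("p < 0.05" and "adj. p < 0.05") differ; the adjusted reading is the more specific and is the default, `use_adjusted = FALSE` restores the raw reading. |
| `de_method` | `"moderated"` | Pooled and Welch kept as fully classical references. |
| `n_trees` | 500 | Forest size; the OOB curve over 1..500 is part of the output. |
| `k` | 30 | Signature size. |
| `measure` | `"gini"` | Importance measure (what the forest's default plot ranks by); `"permutation"` by option. |
| `median_source` | `"self"` | Each cohort is scored against its own medians (the test-set scoring is described independently of training in the source workflow); `"train"` transfers training medians. logFC *signs* are always carried from training. |
| `n_hidden` | 5 | Hidden-layer width. |
| `lr`, `max_epochs`, `tol` | 0.1, 10000, 1e-6 | Full-batch gradient descent; stops when the loss decrease falls below `tol`. The original workflow's optimizer is unstated, so the simplest fully specifiable one is used and exposed. |

## What the synthetic generator emulates — and what it does not

`simulate_study()` draws, per gene, a baseline mean uniform on (4, 12) log2
units and i.i.d. Gaussian noise (sd 0.5) around it, adding ±2 log2 units to
case samples for a planted set of 60 DE genes (half up, half down) out of
2000, with 15 case and 15 control samples — matching the two-group array
design and effect scale the pipeline targets, with a paired 5-vs-5 test
cohort drawn from the same gene-level parameters with fresh noise
(`simulate_paired_cohorts()`). All randomness flows through R's default
Mersenne-Twister via `set.seed()`, so fixtures are byte-reproducible.

It deliberately omits: probe-level artifacts and probe→gene mapping, batch
and normalization effects, missing values, correlated genes, paired
(within-patient) sampling, and heavy-tailed noise. Passing tests on this
generator therefore demonstrate the *software contract* — each stage
computes what it claims under a known truth — not clinical performance on
real cohorts. In particular, a training AUC of 1 on 30 samples with 30
features reproduces a known overfitting regime, not evidence of
generalization; the independent test cohort exists precisely to make that
distinction visible.

## Numerical choices and degenerate inputs

- **Zero-variance genes** (both groups constant): t is undefined; p := 1,
  flagged, never a DEG.
- **Prior-df estimation**: if the observed spread of log variances is below
  its theoretical sampling floor, $d_0 = \infty$ (full shrinkage to a
  common variance); with fewer than 10 informative genes the moderated
  method falls back to pooled with a warning.
- **OOB votes**: a sample never out of bag within the first t trees is
  excluded from that t's denominator; vote ties classify as control (first
  factor level) — fixed so the curve is exactly reproducible by the
  brute-force oracle in the tests.
- **Importance ties** break lexicographically by gene id; the optimal tree
  count breaks ties toward fewer trees.
- **Median ties** score 0 in both directions (strict comparisons).
- **Duplicate gene ids** collapse to the highest-variance row, with a
  warning per id; missing values are rejected unless row-median imputation
  is requested.
- **Weight initialization**: i.i.d. uniform(−0.5, 0.5), biases 0, from the
  seeded RNG; training is fully deterministic given (seed, data,
  hyperparameters). Analytic gradients are verified against central finite
  differences in the tests.
- **Serialization**: expression values are written with 17 significant
  digits so a write/read round trip is bit-exact; artifact writers use
  fixed formatting and the run manifest contains no timestamps, so reruns
  from one configuration are byte-identical.

## Design choices that were genuinely open

- *Unpaired analysis.* Lesional/nonlesional samples may be patient-paired
  in real designs; the workflow models the comparison unpaired, as its
  source methods do. A paired variant is out of scope.
- *Forest input.* The forest is fit on continuous DEG expression, not on
  gene scores: selection precedes scoring in the workflow's order, and
  scoring is defined only for the already-chosen signature.
- *Refit at the optimal tree count?* Unstated in the source workflow; the
  full 500-tree forest is used for importance and the optimum is reported
  as a diagnostic.
- *Probabilities for ROC.* The network's output probabilities (not hard
  votes) feed the ROC, the natural choice for a sigmoid output.
- *Bootstrap AUC confidence intervals* are provided nowhere: no CI method
  is specified for this workflow, and inventing one silently would imply
  precision the design cannot support.

## Problem sizes used by the tests

The suite exercises the full design (2000 genes, 15 + 15 samples, 500
trees) where the contract demands it — contract counts, training AUC,
signature recovery, the 10,000-gene null calibration — and smaller studies
(hundreds of genes, 100-tree forests, 6–12 sample toys) for property-based
and oracle-equivalence tests, chosen so the whole suite completes in well
under a minute while every stage is still covered by an independent oracle:
textbook t formulas, limma, pROC, exhaustive pair counting, brute-force OOB
vote counting, finite-difference gradients, and a per-cell reference
scorer.

## Known limitations

- Gaussian log2-intensity model only; no count (RNA-seq) likelihoods.
- No covariates, batch correction, or paired designs.
- Median dichotomization discards within-sample magnitude; it is the
  workflow's defining statistic, not a recommendation.
- With n = 30 training samples and 30 features, the training-set AUC is an
  optimistic estimate by construction; judge the classifier on the held-out
  cohort.

## A minimal run

```{r example, eval = FALSE}
cfg <- pipeline_config(sim = sim_config(seed = 7))
bundle <- run_training(cfg, out_dir = "artifacts")
held_out <- run_test_evaluation(bundle, out_dir = "artifacts")
held_out$auc
```
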
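---
title: "Methods: MSI screening from indel-length distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MSI screening from indel-length distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msivote)
```

## The problem

Deficient DNA mismatch repair (dMMR) leaves a molecular fingerprint in
tumors: microsatellite instability (MSI), i.e. expansions and — far more
often — contractions of short tandem-repeat tracts, caused by uncorrected
polymerase slippage. Clinically, dMMR status gates immunotherapy
eligibility, so laboratories screen for MSI on the targeted NGS panels they
already sequence. On small panels without a paired normal sample this is
hard: the signal at an individual locus can be a subtle left shift of the
indel-length distribution, well below what single-parameter peak-counting
methods detect reliably.

`msivote` screens tumor-only BAMs by modelling the *full* indel-length
distribution of each microsatellite locus and letting two different
classifiers vote.

## The model

For each locus $\ell$ with reference tract length $L_\ell$ and each sample,
the read evidence is reduced to a profile
$x_{\ell} \in [0,1]^{2w+1}$ indexed by length offset $-w,\dots,+w$:

1. **Read filters.** A read is used iff it is mapped, primary,
   non-duplicate, has MAPQ $\ge$ 20, and its aligned span covers the
   complete tract plus a 5 bp flank on each side.
2. **Observed tract length.** The alignment operations are walked against a
   reference cursor; the read's length is $L_\ell$ plus inserted minus
   deleted bases falling inside the half-open tract $[start, end)$.
3. **Cleaning.** Lengths supported by a single read are removed (these are
   overwhelmingly sequencing noise and needlessly complicate the
   distribution). A locus is *evaluable* in a sample when the remaining
   depth is $\ge$ 30 reads.
4. **Max-normalisation.** Counts are divided by the largest count at the
   locus, so every profile has maximum exactly 1 and depth cancels out.

Per locus, two supervised classifiers are trained on these profiles against
sample-level labels (dMMR = unstable, pMMR = stable; each locus inherits
its sample's label): an L2-regularised (ridge) logistic regression and a
support-vector classifier. Loci are auto-selected in two stages:
coverage (evaluable in $\ge$ 75% of training samples) and discrimination
(validation AUC $\ge$ 0.60 in **both** models). At prediction time a locus
is called unstable only when *both* models call it unstable — the logical
AND suppresses each model's individual false positives. The **sample
score** is the fraction of evaluable loci called unstable, and the default
classification is binary: MSI iff score $> 0.26$ (strict), with an optional
dual-threshold mode that inserts a gray zone between a 95%-specificity
rule-out and rule-in cutoff pair.

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `flank_bases` | 5 | bp | flank a read must fully cover |
| `min_mapq` | 20 | — | minimum mapping quality (inclusive) |
| `min_depth` | 30 | reads | evaluability gate, post-cleaning |
| `singleton_cutoff` | 1 | reads | lengths at or below are removed |
| `coverage_fraction` | 0.75 | — | training-sample fraction for locus retention |
| `locus_auc_min` | 0.60 | — | validation-AUC floor for both models |
| `window` | 20 | bp | profile half-width (vector length 41) |
| `binary_cutoff` | 0.26 | — | sample-score threshold, strict `>` |

The window of ±20 bases is generous: clinically observed shifts on small
panels are well under 20 bp, and a fixed width is required so profiles are
comparable across samples. Observed lengths outside the window are dropped
with a warning rather than clamped, since a clamped pile-up at the edge
would fabricate a spurious mode.

## Training procedure and numerical choices

* **Split.** The labelled cohort is split into train/validation/test
  subsets of near-equal total size, stratified by label; per-class
  remainders go to distinct subsets (train first) so the totals differ by
  at most one. Stratification is imposed so small cohorts keep both classes
  in every subset.
* **Shared folds.** Hyperparameters are chosen by grid search with
  stratified 3-fold cross-validation. The fold assignment is computed once
  over the training samples and shared across loci and model kinds, so
  model comparisons are not confounded by fold luck; a locus's evaluable
  subset keeps the global fold ids.
* **Grids.** Logistic regression: ridge penalty with strength grid
  C ∈ {0.01, 0.1, 1, 10, 100} (internally λ = 1/(C·n)), balanced class
  weights, no standardisation (profiles are already in [0, 1]). SVC:
  linear and RBF kernels crossed with the same cost grid, balanced class
  weights; AUCs are computed from decision-function values, not
  Platt-scaled probabilities.
* **Tie-breaking.** With small, well-separated training sets many grid
  points reach the same cross-validated AUC, and AUC cannot distinguish
  them because it only sees ranks. Ties are broken toward the canonical
  moderate regularisation (C closest to 1, then grid order): the extreme
  grid points yield degenerate decision boundaries whose *binary* calls —
  which the voting step consumes — are essentially noise even though their
  rankings are perfect.
* **Per-locus calls.** Each model's native decision is used: probability
  ≥ 0.5 (equivalently, log-odds ≥ 0) for the logistic model, the
  decision-function side for the SVC. No per-locus threshold tuning is
  performed; the sample-level cutoff absorbs calibration.
* **Outlier/"zoo" models.** One-class SVM, naive Bayes and random forest
  are available behind the same interface for model comparisons (the
  one-class SVM sees stable-labelled profiles only). They never enter a
  bundle: random forests overfit individual loci badly at these sample
  sizes, and the supervised pair dominated the alternatives.
* **Degenerate inputs.** Empty distributions cannot be normalised (error);
  a locus whose validation subset is single-class is dropped with a
  warning; a sample with zero evaluable loci is refused, while one with
  fewer than half the retained panel is scored but flagged
  low-confidence — clinical users need the result plus a caveat, not a
  refusal.
* **Dual thresholds.** Candidate cutoffs are the observed scores; positive
  calls use strict `>` everywhere. When one cutoff already meets both
  targets the raw rule-out bound exceeds the raw rule-in bound; both are
  then clamped to their midpoint (empty gray zone) with a warning, and the
  raw optima are reported alongside.
* **Determinism.** All randomness (split, folds, simulation) flows from
  explicit seeds; generators save and restore the caller's RNG state.
  Bundle manifests contain no timestamps, so a fixed seed reproduces them
  byte for byte.

## The synthetic cohort generator

No public clinical cohort accompanies the method, so the package ships a
generator that emulates the data-generating process the screen targets:

* **Stutter.** Each read reports the allele length plus a slippage offset:
  0 with probability $1-p$ ($p = 0.05$), otherwise a geometric magnitude
  (decay 0.5) that is a contraction with probability 0.8 — matching the
  contraction-dominated stutter of mononucleotide tracts and the
  predominance of left-shifted MSI distributions.
* **MSI.** In a dMMR sample, 80% of panel loci are shifted: a `purity`
  fraction (default 0.5) of reads is drawn around the contracted tumor
  allele (`msi_shift` = 6 bases below reference), the remainder from the
  stable process — the mixture a 50%-pure tumor would produce.
* **Depth.** Poisson with mean 200 per locus, typical of small capture
  panels after deduplication.

`write_bam_fixture()` materialises a simulated sample as a sorted, indexed
BAM whose CIGAR strings encode the simulated indels, plus optional decoy
reads that each violate exactly one read filter; the extraction pipeline
recovers the simulated distributions exactly on decoy-free fixtures, which
is what the round-trip tests assert.

What the generator does **not** emulate: substitution errors, quality
strings, FFPE deamination artifacts, paired-end geometry, mappability
variation between loci, and inter-locus correlation of instability within
a sample (each locus shifts independently). Passing tests therefore
demonstrate the statistical machinery — filters, feature construction,
selection, voting, thresholds — under a realistic noise model, not
performance on real tumor data, which additionally contends with those
artifacts.

## Problem sizes used in the test suite

The end-to-end tests use a 28-locus panel with cohorts of 133 stable + 46
unstable samples (the scale at which per-class thirds give ~60-sample
subsets), evaluated over 50 seeds; the robustness comparison contrasts the
smallest (20-10:10-5) and full-size (45-16:43-15) train:validation designs
over 10 simulations each. These sizes exercise every selection boundary
while keeping a full run on a laptop in minutes.

## A worked example

```{r example, eval = FALSE}
library(msivote)

panel <- synthetic_panel(28)
cfg <- msi_config(seed = 1)

cohort <- simulate_cohort(panel, n_stable = 133, n_unstable = 46,
                          sim_params(), seed = 1)
cf <- cohort_features(cohort, panel, cfg)

bundle <- msi_train(cf, panel, cfg)
glance(bundle)

test <- cf[bundle$split$subset == "test", ]
scored <- predict_cohort(test, bundle)
roc_auc(scored$score_combined, scored$label)
diagnostic_metrics(scored$score_combined, scored$label, 0.26)

autoplot(bundle)
```

## Known limitations

* Locus labels are inherited from the sample label, but not every locus of
  a dMMR tumor is truly unstable; the per-locus AUC filter compensates
  only partially, and loci that are rarely shifted in a given tumor
  spectrum will be dropped rather than modelled.
* Tumor purity below ~20% dilutes the mixture beyond what locus models
  trained on higher-purity cohorts detect; the package neither estimates
  nor corrects for purity.
* The binary cutoff of 0.26 is a property of the published protocol's
  panel and cohort; a new panel should re-derive cutoffs with
  `dual_thresholds()` / `diagnostic_metrics()` on its own validation data.
* Bundles store fitted R model objects; they are reloadable only under a
  matching package version (the loader enforces this rather than guessing).
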
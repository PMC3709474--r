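---
title: "Decoding stimulus conditions from BOLD response patterns: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding stimulus conditions from BOLD response patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boldmvpa)
```

## The analysis in one paragraph

`boldmvpa` implements multivoxel pattern analysis (MVPA) of event-related
fMRI: within a region of interest (ROI), the spatial pattern of the
normalized BOLD response to each stimulus is treated as a point in a
voxel-dimensional space, and a linear support vector machine (SVM) is asked
to separate the patterns evoked by different stimulus conditions.
Classification is cross-validated by leaving one acquisition run out at a
time; group-level significance is assessed by comparing the observed
group-average accuracy with a null distribution obtained by re-running the
entire cross-validated analysis on label-shuffled data. Because every trial
pattern is standardized across voxels before classification, a successful
classification cannot be driven by bulk amplitude differences between
conditions (saliency, arousal, global gain): it necessarily reflects
differences in the fine-grained spatial distribution of the response. A
companion simulator generates synthetic 4D datasets with known
condition-specific patterns so that every stage of the pipeline can be
validated quantitatively without human data.

## The data model

A trial pattern is built as follows.

1. **Simulation (or acquisition).** Each voxel's time series is a linear
   superposition of event responses: the condition's voxel amplitude times
   a canonical double-gamma hemodynamic response function (HRF) shifted to
   the event onset, plus linear drift and white Gaussian noise. The HRF
   is the difference of two gamma densities (positive lobe shape 6,
   undershoot shape 16, scales 1 s, undershoot ratio 1/6), peak-normalized
   to 1; its peak lies at 5.0 s after the event. Signals are sampled at
   volume mid-acquisition times.
2. **Detrending and normalization.** Within each run, every voxel's series
   has its least-squares intercept and slope removed (`detrend_run`) and is
   then z-scored (`preprocess_dataset`). Because folds are whole runs,
   these run-wise statistics never cross a train/test boundary.
3. **Volume selection.** With TR = 3 s and inter-stimulus intervals of
   10–19 s, the volume acquired roughly 4–6 s after onset contains the
   response peak. `select_trial_volume` maps onsets to volumes by window
   containment: volume `k = 0` is the volume whose acquisition window
   contains the onset, and `k >= 1` the k-th complete volume beginning
   after onset. The exact onset-to-grid convention used in any given lab
   is rarely recoverable from a paper's text, so a `ceil` alternative is
   provided and the convention is an explicit argument.
4. **Pattern standardization.** Each trial's row (one value per ROI voxel)
   is centred and scaled to unit standard deviation across voxels. This
   per-trial step is what guarantees gain invariance: multiplying all of
   one condition's volumes by any positive constant leaves the extracted
   patterns — and hence every downstream accuracy — unchanged, a property
   the test suite asserts to numerical tolerance.

The normalization chain is deliberately split into two independently
toggleable steps (per-voxel z-scoring within run; per-trial
standardization), since published descriptions of "normalization" in this
family of analyses are usually under-specified. The default applies both.

## Decoding

`crossvalidate_two_way` trains LibSVM's linear C-SVM (through e1071, with
`scale = FALSE` so the package's own normalization is the only one applied)
on all runs but one and classifies the held-out run, rotating over runs.
Accuracy is the fraction of correct guesses among held-out trials; the
summary accuracy is the unweighted mean over folds. The regularization
constant defaults to C = 1, a common neuroimaging choice; the pipeline's
statistical guarantees (chance calibration, gain invariance) are asserted
in the tests for C in {0.1, 1, 10}. Weights are re-oriented so that a
positive decision value always predicts the first condition of the pair,
making weight maps comparable across folds and subjects.

`crossvalidate_four_way` performs multiclass classification by pairwise
voting: all six pairwise classifiers predict every held-out trial and the
most-predicted label wins. Vote ties are resolved uniformly at random among
the tied labels using the seeded RNG stream; a deterministic `lowest`
mode exists for exact tests and is used inside the permutation engine so
that identical label assignments always give identical accuracies. Results
accumulate into a guesses-by-targets confusion matrix whose columns sum to
the per-condition test counts.

## Inference

`permutation_test` shuffles condition labels *within each run of each
subject*, recomputes the full cross-validated decoding per subject, and
records the group-average accuracy; repeating this builds the null. Within-
run shuffling is chosen to preserve run-level exchangeability under
leave-one-run-out cross-validation (shuffling across runs would break the
balance that the fold structure assumes); labels are never mixed across
subjects. By default both training and testing labels are permuted, with a
`train-only` scope available. The p-value convention is
`count(null >= observed) / n`, reported as "P < 1/n" when no permutation
reaches the observed accuracy; a conservative `(count+1)/(n+1)` mode is
available. Permuted decodings are memoized per distinct label assignment —
an exact optimization, since the decoder is deterministic, that makes
small-sample permutation tests effectively exhaustive at no statistical
cost.

`wilcoxon_paired` compares matched per-subject accuracies (for example
pertinent versus non-pertinent tasks). For 25 or fewer informative pairs
the null distribution of the signed-rank statistic is built exactly by
convolution over the midranks of the absolute differences — this retains
exactness under tied magnitudes, where classical tables do not apply —
and the normal approximation with tie correction is used above. Zero
differences are uninformative and dropped; all-zero input is an error.

`saliency_accuracy_correlation` computes Spearman's rho with midranks and
a seeded permutation p-value, used as a control that accuracy differences
do not track stimulus saliency differences.

## Sensitivity maps, dissimilarity, and GLM characterization

Subject-level sensitivity maps are the fold-averaged linear SVM weights.
`group_f_map` tests each voxel's weight against zero across subjects with
a one-sample F test (the squared t), df (1, n−1); with 14 subjects the
5% critical value is 4.67. Voxels with zero weight in every subject are
undefined and excluded; zero-variance voxels with non-zero mean receive an
infinite-F sentinel with a warning rather than a silent number. Map
dissimilarity between tasks is 1 − Pearson r over shared voxels (NaN
voxels excluded pairwise; zero-weight voxels retained, as they are
informative). `glm_betas` fits the conventional univariate GLM (HRF-
convolved condition regressors plus per-run intercept and linear drift,
ordinary least squares) to characterize whether contributing voxels carry
positive responses, negative responses or a mixture.

## What the simulator emulates, and what it does not

The generator reproduces the *design* of the emulated study: 4 runs of 32
events (8 per condition, four conditions), inter-stimulus intervals drawn
uniformly from 10–19 s, never more than two consecutive events of the same
condition (rejection sampling with a greedy constructive fallback), TR 3 s.
Condition-specific signal is injected as sparse Gaussian voxel-amplitude
maps inside cubic ROIs within a synthetic box-shaped brain; default
sparsity 0.5 and unit amplitude standard deviation are placeholders chosen
to give moderate single-trial signal-to-noise at unit white noise, not
estimates of cortical pattern statistics, which no desk-scale source
provides. Noise is white plus per-run linear drift (slope sd 0.02 signal
units/volume); there is no physiological noise, no spatial autocorrelation,
no scanner artefacts, and no subject-to-template registration step (all
simulated subjects share one grid). Consequently, passing tests demonstrate
the *correctness and calibration of the analysis machinery* — chance
levels, type-I error, recovery of injected signal, invariances — not that
any particular real-data accuracy level would be reproduced.

## Numerical and degenerate-input choices

- Onsets are seconds from run start; volume `j` spans `[j·TR, (j+1)·TR)`
  with 0-based indices; sampling uses mid-volume times.
- Trials whose extraction volume falls beyond the run are dropped with a
  warning, never imputed; zero-variance pattern rows and sub-2-voxel ROIs
  are errors naming the offender.
- Mask erosion peels voxels with any face (6-connectivity) neighbour
  outside the mask — the most conservative single-layer peel; 26-
  connectivity is available behind a flag. Eroding to emptiness is an
  error advising a larger ROI.
- The out-of-brain control region samples exactly the rounded mean ROI
  size, so its (chance-level) accuracies are directly comparable.
- Rank-deficient GLM designs fail with the collinear columns named.
- All random draws derive from explicit integer seeds; identical
  configurations reproduce reports byte for byte.

## Problem sizes

The default `ci` study profile uses 6 simulated subjects and 1,000
permutations with small cubic ROIs, sized so that a complete experiment
runs in minutes on a single CPU; a `paper` profile (14 subjects, 10,000
permutations) matches the emulated study's scale. The test suite's
calibration checks use 50 replicate null datasets of 6 subjects for chance
levels, 200 null datasets at 1,000 permutations for the type-I error of the
permutation test, and 20 simulation seeds for signal recovery; these sizes
are the package's chosen trade-off between statistical resolution of the
checks and a suite that runs comfortably on one core.

## Known limitations

- The linear-SVM weight map is a sensitivity map, not a causal or
  univariate activation map; its sign convention is only meaningful
  relative to the task's condition order.
- The permutation engine recomputes the full decoding per permutation;
  at paper scale (10,000 permutations × 14 subjects) this is hours of
  compute, which is inherent to the method rather than to this
  implementation.
- The simulator's noise model is deliberately simple; effect sizes
  calibrated on it do not transfer to real data.
- Pooled-condition tasks assume the pooled labels remain balanced within
  runs, which the balanced design guarantees; unbalanced designs are not
  currently supported by the permutation engine's within-run shuffle.
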
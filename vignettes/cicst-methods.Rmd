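---
title: "Cost-sensitive thresholding for multi-label ECG classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-sensitive thresholding for multi-label ECG classification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cicst)
```

## The problem

Automatic ECG interpretation is a multi-label task: a recording can carry
several coexisting diagnoses (say, atrial fibrillation together with a bundle
branch block), the label vocabulary is large, and category frequencies span
orders of magnitude — sinus rhythms are abundant while many arrhythmias are
rare. It is also cost-sensitive: calling an atrial fibrillation "atrial
flutter" still routes the patient towards appropriate care, while calling it
"normal" hides the disease. A binary-relevance deep model (one sigmoid head
per category over a shared representation) produces a score in $[0,1]$ per
category; everything clinically consequential then hinges on where each
score is cut.

This package implements that cutting step — category imbalance and
cost-sensitive thresholding (CICST) — together with the metric it targets,
baseline thresholding strategies, the signal pre-processing chain, a compact
reference network, and synthetic generators so the whole pipeline can be
studied end to end without any clinical corpus.

## The model

### From a benefit matrix to per-category costs

Expert knowledge enters as a benefit matrix $B \in [0,1]^{m \times m}$ with
$B_{ij}$ the benefit of predicting category $i$ when the truth is $j$;
$B_{ii} = 1$, and high off-diagonal entries mark diagnoses with similar
outcomes or treatments. Its complement $C' = 1 - B$ is a pairwise
misclassification cost matrix.

Binary-relevance detectors need scalar false-positive and false-negative
costs per category, not a pairwise matrix. Fixing the false-negative cost at
1, the representative false-positive cost $c'_j$ averages the pairwise costs
over the training label distribution: each training recording's labels are
row-normalized ($Y_n = Y / \max(\text{row sum}, 1)$, so a label-free
recording contributes nothing), the per-recording cost of predicting each
category is $SC' = Y_n C'$, correct predictions are masked out
($SC'' = SC' \odot (1 - Y)$), and $c'_j$ is the mean of $SC''_{\cdot j}$
over the negative recordings of category $j$. A category with no negative
recordings can never be a false positive; its cost is set to 0 with a
warning.

### Blending with class imbalance

The imbalance ratio $IR_j$ (negatives over positives) summarizes how skewed
each detector's training task is. The final cost interpolates in log space,

$$c_j \;=\; (c'_j)^{\alpha}\, IR_j^{\,\alpha - 1},$$

with a modulating factor $\alpha \in [0,1]$: $\alpha = 1$ keeps the
predefined costs exactly, $\alpha = 0$ gives $c_j = 1/IR_j$ — the rarer the
category, the cheaper a false positive and hence the lower its threshold,
which is what pushes sensitivity onto rare diseases. The literature this
method descends from states the two endpoint roles inconsistently with its
displayed formula, so both readings exist in the wild; the package makes the
convention explicit (`convention = "cost"` as above, `"mirror"` for the
swapped reading with $\alpha \leftrightarrow 1-\alpha$) and defaults to
$\alpha = 0.3$, inside the 0.2–0.4 band where validation scores typically
peak. `0^0` is defined as 1, so a zero predefined cost still yields $1/IR$
at the pure-imbalance endpoint.

By default $IR$ is Laplace-smoothed, $(\#\text{neg}+1)/(\#\text{pos}+1)$, so
a category absent from the training set keeps a finite ratio (and therefore
a usable threshold); `smoothing = FALSE` errors instead. $IR$ is computed on
whatever label matrix is passed as the training set; when used inside
cross-validation, that is the training fold.

### Thresholds

For a detector with zero cost for correct calls, false-negative cost 1 and
false-positive cost $c$, the expected-cost-minimizing rule on a calibrated
posterior $p$ is "predict positive iff $p > c/(1+c)$". CICST therefore sets
$t_j = c_j / (1 + c_j) \in [0,1)$, monotone in $c_j$. The comparison is
strict ("larger than the threshold"), which matters for saturated scores: a
score exactly at the threshold is negative.

Because thresholds are pure post-processing, a change in the cost definition
(a revised benefit matrix) only requires recomputing $t$ — `update()` on a
fitted object — not retraining the classifier. The
`cost_change_adaptation()` experiment measures exactly this.

### The metric

`cwacc()` implements the cost-weighted accuracy used by recent ECG
challenges. Multi-label predictions are organized in a generalized
confusion matrix: a recording with annotated set $L$ and predicted set $P$
adds $1/|L \cup P|$ to every cell $(i \in P, j \in L)$. The raw score
$\sum_{ij} a_{ij} b_{ij}$ is normalized so that a perfect classifier scores
1 and the trivial always-normal classifier scores 0, with both anchors
computed on the recording set being scored. Whether recordings with empty
annotated *and* predicted sets contribute is not pinned down by the public
definitions; this implementation uses $\nu = 1$ for that case and documents
it as the in-repo convention (exact agreement with any external evaluation
code is not asserted). Alongside it: exact-match accuracy and micro-averaged
sensitivity/specificity.

### Baselines

Rcut assigns each recording its `t_count` top-scoring labels (typical label
cardinality ~2); Pcut marks, per category, the top $k_j =
\text{round}(\text{prevalence}_j \times N)$ scoring recordings positive;
fixed thresholding cuts everything at one constant (0.5 by convention, 0.2
as a tuned variant). Ties resolve to the lower category/recording index and
$k_j$ uses banker's rounding — both choices are arbitrary where the
conventions are silent, and are fixed for reproducibility. Recordings may
end up with no predicted label; no fallback label is asserted by default
(the CLI has an opt-in `--assert-normal`).

## Pre-processing

`preprocess_ecg()` maps any multi-lead record to a `5000 x l` matrix at
250 Hz: resample → remove baseline → band-pass 0.1–50 Hz → standardize →
fix length at 20 s. Choices where standard practice had to fill gaps:

* **Resampling** — anti-alias zero-phase Butterworth low-pass (order 5,
  cutoff $0.45 \times$ target rate) before cubic-spline interpolation onto
  the target grid. This handles arbitrary (non-rational) rate ratios
  cleanly; on pure tones it tracks the analytic reference with correlation
  > 0.999.
* **Baseline removal** — centered one-second moving average (250 samples)
  with reflection padding, subtracted per lead; shift-free by construction.
* **Band-pass** — cascade of zero-phase Butterworth high-pass (order 2 at
  0.1 Hz) and low-pass (order 5 at 50 Hz) rather than a single band-pass
  design: a ten-pole band-pass whose lower edge sits at $8 \times 10^{-4}$
  of Nyquist is numerically fragile, and the order-5 low-pass is what
  delivers ≥ 90% attenuation of 60 Hz mains interference after
  forward-backward filtering while holding 10 Hz (QRS-band) gain within 5%.
* **Standardization** — per lead, population variance, zero-variance leads
  zeroed with a warning. Per-lead (rather than whole-recording)
  normalization is the documented reading of "normalized to zero mean and
  unit variance".
* **Order** — standardization precedes length-fixing so appended zeros do
  not distort the lead statistics; truncation keeps the first 20 s, padding
  appends zeros.

## The reference network

The classifier is a 1D full-pre-activation residual network: each block is
BN → ReLU → conv → BN → ReLU → conv with an additive shortcut (1×1
projection when channel counts change) followed by max-pooling (width and
stride 2, halving the time axis). The resulting feature map
$V \in \mathbb{R}^{b \times t \times f}$ is pooled per category by
class-wise attention: a 1×1 convolution produces one key channel per
category, one-hot queries select their channel, a softmax over time yields
attention weights (non-negative, summing to 1), and each category's feature
vector is the weight-averaged feature map — so different categories can
attend to different beats. A dedicated fully connected sigmoid head per
category emits the score. No $\sqrt{d}$ attention scaling is applied:
with one-hot queries it would be a constant and cancel inside the softmax.

Because no deep-learning framework is part of this package's dependency
set, forward and backward passes are written in base R matrix algebra
(im2col convolutions, hand-derived gradients, verified against finite
differences to ~1e-7). Training follows the standard recipe: unweighted
binary cross-entropy, Adam with $\beta_1 = 0.9$, $\beta_2 = 0.999$, initial
learning rate 0.001 and per-epoch exponential decay by 0.9. Architecture
defaults (6 blocks, 32→64 filters, kernel 15, batch 32, 20 epochs) are
desk-scale and fully configurable; the test suite trains a deliberately
small configuration (4 blocks, 8 filters, kernel 9, 6 epochs, 120 training
records) that separates two synthetic rhythm classes to micro-Se/Sp ≥ 0.9
in a few minutes on one CPU. Given identical data and config (including the
seed, which drives both initialization and batch shuffling), training is
bit-reproducible.

## Synthetic data: what it does and does not show

The generators exist so every claim in this package is testable without a
clinical corpus:

* `gen_label_matrix()` draws per-category Bernoulli labels at target
  prevalences (imbalance ratios up to ~1000), optionally tilted by pairwise
  co-occurrence odds multipliers applied sequentially in category order —
  an approximation adequate for producing correlated label sets, not a
  maximum-entropy joint model.
* `gen_calibrated_scores()` models a classifier whose scores are true
  posteriors: per cell, $p \sim \text{Beta}(\pi/h, (1-\pi)/h)$ (mean $\pi$,
  the category prevalence) and, in `"resample"` mode, the label is redrawn
  as Bernoulli($p$) — calibration is then exact by construction, which is
  what makes the threshold-optimality tests sharp. `"fixed-label"` mode
  keeps the given labels and draws from the matching conditionals
  $\text{Beta}(a + y, b + 1 - y)$. The sharpness $h$ tunes informativeness
  ($h \to \infty$: scores collapse to $\{0,1\}$; $h \to 0$: scores collapse
  to the prevalence); the default $h = 1$ plays the role of a moderately
  informative classifier.
* `gen_benefit_matrix()` builds clustered similarity structure (within- vs
  between-cluster benefit), `perturb_benefit()` rescales the rows/columns
  of a random half of the categories to simulate a revised cost definition.
* `gen_ecg()` synthesizes multi-lead waveforms as Gaussian-wavelet beat
  trains (P, QRS, T bumps) on an RR-interval process; labels modulate rate
  (tachycardic/bradycardic), RR irregularity and P-wave absence (AF-like),
  and wide-complex ectopic insertion (PVC-like), plus configurable noise
  and baseline drift. This is deliberately minimal — enough temporal
  structure to exercise convolution, pooling and attention, with no
  biophysical pretension.

The standard experiment conditions (`synthetic_scenario()`) are 16,000
training and 4,000 validation recordings, $m = 10$ categories with
imbalance ratios log-spaced from 3 to 300, a 3-cluster benefit matrix
(within 0.5, between 0.1) and sharpness 1. Under these conditions the test
suite reproduces the qualitative behaviour expected of the method: CICST
dominates fixed 0.5 thresholding on cost-weighted accuracy and sensitivity,
the CWAcc-vs-$\alpha$ curve has an interior maximum, and re-deriving
thresholds after a cost change is (weakly) beneficial in ≥ 95% of
perturbations. Passing these tests says the machinery is correct and the
qualitative claims hold *under calibrated scores and this label model*; it
says nothing quantitative about any real corpus, where scores are
miscalibrated in structured ways, labels are noisy and prevalences shift
between sites.

## Numerical choices

* All cost arithmetic is double precision. The matrix product inside the
  cost derivation is accumulated column-by-column in fixed label order, so
  results are bitwise-reproducible and independent of the BLAS — the test
  suite asserts *exact* equality against an elementwise loop oracle.
* Softmax in the attention layer subtracts the per-series maximum before
  exponentiation.
* Batch normalization uses batch statistics during training (momentum 0.9
  running moments for inference) with $\epsilon = 10^{-5}$; batches of size
  1 are skipped.
* Binary cross-entropy clips probabilities at $10^{-7}$.
* Degenerate inputs are warnings, not failures, where a sensible value
  exists: categories with no negatives (cost 0), zero-variance leads
  (zeroed), all-normal datasets (`cwacc` 0), records shorter than the
  baseline window (window shrinks).

## Known limitations

* Converting the pairwise cost matrix to scalar binary costs loses
  information by design; categories whose costs depend strongly on *which*
  wrong label is predicted are summarized by an average.
* The union-normalized confusion matrix is one member of a family of
  multi-label generalizations; scores are comparable within this package,
  not across implementations with different conventions.
* The co-occurrence model in the label generator is order-dependent; the
  ECG generator is a caricature (no PQRST morphology variation across
  leads beyond amplitude scaling, no realistic noise spectra).
* The reference network is desk-scale: it demonstrates the architecture
  and training recipe, not competitive classification performance.
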
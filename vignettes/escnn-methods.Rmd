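---
title: "Subgroup-ensemble sleep staging: models, parameters and design notes"
author: "escnn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subgroup-ensemble sleep staging: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

Sleep staging assigns one of five AASM stages (Wake, N1, N2, N3, REM) to each
30-second epoch of an overnight EEG. A single classifier trained on a pooled
cohort treats every subject as exchangeable, but the spectral expression of
the stages differs between people — alpha-rich versus alpha-poor wake EEG,
for example — and subjects far from the pooled average are staged poorly.
`escnn` addresses this with a three-part pipeline:

1. **Spectral subgrouping.** Each subject is summarised by 13 features:
   absolute band power and mean spectral density in the delta (0.5–4 Hz),
   theta (4–8), alpha (8–13), beta (13–30) and gamma (30–35 Hz) bands, plus
   three fast/slow-wave power ratios (alpha/delta, beta/theta,
   (alpha+beta)/(delta+theta)). Features are z-scored, reduced to `U = 3`
   principal components, and the cohort is partitioned by Euclidean k-means.
   The number of subgroups `k` is chosen by the mean silhouette coefficient
   over candidates `k = 2..5`, ties resolved toward the smaller `k`. The
   retention of information of the PCA truncation — the fraction of
   eigenvalue mass kept — is reported alongside.

2. **One sequential CNN per subgroup.** The night is encoded as overlapping
   windows of `L = 10` adjacent epochs (stride one epoch), giving a
   `(P-L+1) x L x M` tensor. The network has two convolutional branches:
   a small-scale branch (kernel width `fs/2` samples, stride `fs/16`)
   tuned to fast activity, and a large-scale branch (width `4*fs`, stride
   `fs/2`) tuned to slow waves. Both convolve with **kernel height 2 over
   the epoch axis**, so every window position is scored from the pair of
   adjacent epochs it anchors — this is how inter-epoch context enters.
   Each branch continues with max-pooling (8, then 4), two width-8
   convolutions at twice the branch filter count, squeeze-and-excitation
   (SE) recalibration (global average pool over the width axis, an
   `O -> O/r -> O` bottleneck with ReLU, a sigmoid gate per channel
   multiplied back onto the features), and global average pooling. The
   concatenated branch features feed a linear head shared across window
   positions, yielding per-position stage logits.

3. **Decoding and ensemble fusion.** Per-position probability rows are
   L1-normalised, and all rows covering the same absolute epoch are summed
   (a sequence-decoding step that makes the consolidation independent of
   the classifier's calibration). For a test subject, the distance to each
   subgroup is the mean Euclidean distance from the subject's PCA
   coordinates to the subgroup's members, and the per-subgroup consolidated
   scores are fused with normalised inverse-squared-distance weights
   `w_i = (1/D_i^2) / sum_j (1/D_j^2)` before the final argmax (ties break
   toward the lower stage index, in the order Wake, N1, N2, N3, REM).

Evaluation uses leave-one-subject-out (LOSO): PCA, clustering and all
networks are refitted for every fold with the test subject excluded, so no
information about the test subject reaches training. The package reports
accuracy, Cohen's kappa from the confusion marginals, one-vs-rest F1,
sensitivity and specificity per stage with macro averages, and rank-based
one-vs-rest AUC (equal to the trapezoidal ROC area).

# Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `L` | 10 epochs | sequence window length; epochs get up to `L` overlapping predictions |
| `U` | 3 | principal components kept for clustering |
| `kRange` | 2–5 | candidate subgroup counts scored by silhouette |
| `smallKernelW`, `largeKernelW` | `fs/2`, `4*fs` samples | the two convolutional scales (0.5 s and 4 s of signal) |
| `kernelH` | 2 epochs | cross-epoch convolution height; `1` ablates inter-epoch context |
| `nFilters` | 64 (8 in the desk-scale experiments) | first-layer filters per branch |
| `seReduction` | 16 (4 at desk scale) | SE bottleneck ratio; must divide `nFilters` |
| `dropout` | 0.3 | dropout on the concatenated features during training |
| `lr`, `batchSize` | 1e-3, 32 | Adam settings |
| `maxEpochs`, `patience` | 30, 5 | training-epoch cap and early-stopping patience |
| `restarts`, `restartFloor` | 1, 0.9 | seeded training restarts and the validation accuracy that ends them |
| notch / band-pass | 50/60 Hz optional; 0.3–35 Hz | preprocessing filters, zero-phase |

# Numerical and algorithmic choices

* **Welch PSD**: 4-second Hann windows with 50% overlap, density scaling,
  per-segment demeaning; the one-sided estimate integrates to the signal
  variance. Band powers are trapezoidal integrals of the density with
  linear interpolation at band edges; ratio denominators are floored at
  1e-12.
* **Filters**: the band-pass is a 4th-order Butterworth applied
  forward–backward (zero phase); the notch is a second-order IIR biquad
  with quality factor 30, also zero-phase. Filtering precedes
  whole-recording z-normalisation, which is idempotent.
* **PCA**: column z-scoring (scale floored at 1e-12 with a warning for
  constant features), eigendecomposition of the covariance, deterministic
  component signs (largest-magnitude loading positive). All eigenvalues are
  stored so the retention of information is available for any `U`.
* **k-means**: 10 seeded restarts, best inertia kept; `k` equal to the
  number of subjects degenerates to singleton subgroups without calling the
  base optimiser. All-identical points raise a degenerate-data error.
* **Silhouette**: the standard form — per-point mean intra-cluster distance
  `a`, nearest-other-cluster mean distance `b`, score `(b-a)/max(a,b)`,
  singletons contributing zero. An O(S^2) brute-force double loop serves as
  the test oracle.
* **Subgroup distance**: `clusterDistances()` defaults to the mean distance
  to the subgroup's members (the subgroup-distance definition), with the
  centroid alternative via `mode = "centroid"`. The LOSO driver fuses with
  centroid distances by default: the fusion weights are defined on
  distances to the clustering centres, and member-mean distances fold
  within-subgroup spread into every distance, diluting the weights. Zero
  distances send the full fusion weight to the nearest subgroup, split
  uniformly among exact ties.
* **Training reformulation**: because no layer mixes window positions
  beyond the height-2 pairing and the classifier head is shared, the
  window-sum cross-entropy decomposes exactly over the distinct epoch pairs
  of each recording, weighted by how many (window, position) slots cover
  each pair. Training therefore iterates over weighted epoch pairs — an
  exact, roughly L-fold cheaper restatement of the same loss. The final
  window position pairs the window's last epoch with zero padding; those
  pad pairs are part of both training and inference.
* **Validation for early stopping** is carved from the trailing epochs of
  each training recording (default 15%) rather than by random pair
  sampling: adjacent pairs share epochs, so a random split would leak
  training epochs into validation and early stopping would track the
  training set.
* **Initialisation**: the first-layer filters of each branch start as
  Hann-windowed sinusoids at log-spaced frequencies (4–35 Hz for the small
  branch, 0.5–16 Hz for the large), plus a little seeded noise — each
  branch opens as a crude filter bank instead of waiting for random filters
  to acquire band selectivity, which removes most attempt-to-attempt
  variance in what the network learns. Later layers use He-scaled seeded
  Gaussians; the classifier head starts small (sd 0.05) so untrained
  predictions sit near the uniform prior while the trunk still receives
  gradient early on.
* **Restarts and attempt averaging**: small networks occasionally settle in
  poor optima, and same-subject validation cannot flag every such failure.
  With `restarts > 1` training repeats from fresh seeded initialisations
  until an attempt reaches `restartFloor` validation accuracy (or the
  budget is exhausted); the best-validation attempt provides the model's
  parameters, and prediction averages the probabilities of all attempts
  within 0.05 validation accuracy of the best — a small deep ensemble that
  damps the residual variance.

# The synthetic cohort generator

Real polysomnography is licensed and large; the generator provides seeded
cohorts in which every pipeline claim can be tested end to end. Each subject
receives a Markov hypnogram (first epoch Wake) and per-epoch signals built
from band-limited noise whose variance shares follow a per-stage profile,
plus a broadband noise floor; epochs are normalised to unit variance.
The default stage signatures follow textbook sleep EEG: Wake
alpha/beta-dominant, N1 theta-dominant, N2 theta-dominant with two 1-second
13 Hz spindle bursts per epoch, N3 delta-dominant, REM mixed theta/beta,
each with a 0.15 broadband floor. Two small calibrations keep each
profile's declared dominant band dominant in *measured* per-epoch power:
the spindle amplitude is modest (so N2 stays theta-led despite the 13 Hz
bursts), and REM's theta weight exceeds its beta weight by enough to cover
the broadband floor's bandwidth-proportional contribution to the wide beta
band. The default transition matrix is doubly stochastic with
self-transition 0.75 and the rest spread uniformly: bouts last about four
epochs, so most adjacent-epoch pairs share a stage (the regime the
cross-epoch convolutions are built for), and the stationary stage
distribution is exactly uniform, so every stage is well represented in
every subject's night — a drifting chain that starves a stage in one
subject both cripples small training subgroups and distorts the
subject-mean features.

Spectral subgroups are created by multiplying the alpha and beta profile
weights of group *g* by `groupShift^(g-1)` (default shift 3) and
renormalising — the fast/slow-wave axis the clustering features measure.
The shift is deliberately large: the ensemble's premise is a cohort whose
subgroups express stages differently enough that one pooled model is a
compromise.

Two design notes from calibrating the generator, recorded here because they
are properties of the method, not of the implementation:

* **Night composition confounds the subject summary.** The 13 features are
  means over all scored epochs, so two subjects with identical spectral
  identity but different stage proportions produce different feature
  vectors, and column z-scoring amplifies any such composition variance to
  unit scale regardless of its raw size. Subgroup recovery is therefore
  only reliable when night compositions are comparable across subjects —
  true of real cohorts of healthy sleepers, and of generated cohorts whose
  chain mixes quickly. The recovery property tests use strongly mixing
  chains for this reason, while classification experiments keep the
  persistent default chain (the cross-epoch convolution sees mostly
  same-stage pairs, as in scored sleep).
* **Silhouette selection of `k` is fragile on tiny subgroups under
  composition noise.** With three subjects per subgroup and divergent night
  compositions, isolating one slightly-distant subject as a third cluster
  can out-score the true `k = 2` even when the two-group assignment is
  perfect; with comparable compositions (mixing chain) the selection is
  reliable at the default cohort size. The end-to-end staging experiments
  keep the persistent chain, where fold accuracy, not k-selection, is the
  claim.

The generator does **not** emulate K-complexes, artifacts, age effects,
sleep-cycle periodicity (bouts are geometric, not 90-minute cycles), or
inter-subject variability beyond the subgroup shift. Passing tests show the
pipeline recovers structure it was designed to see; they say nothing about
scorer-level performance on recorded polysomnography.

# Problem sizes used by the test-suite and acceptance script

All sizes were chosen as desk-scale reference conditions and are fixed in
the tests: the end-to-end LOSO experiment uses 6 subjects (two subgroups of
three) with 200 scored epochs each at 100 Hz and a tiny network
(`nFilters = 8`, `seReduction = 4`, at most 20 training epochs, patience 6,
up to 4 restarts with floor 0.97); the ensemble-versus-pooled comparison
uses five seeded cohorts of 6 subjects with 120 epochs each, one held-out
fold per cohort alternating between the subgroups; `scripts/acceptance.R`
runs the full 6-fold LOSO with the pooled ablation at the 200-epoch
reference scale (subject-mean features need that many epochs for night
compositions, and hence the subgroup clustering, to be stable). Unit tests use 80 Hz cohorts (the gamma band still clears Nyquist)
and 30–40 epochs where the claim under test does not depend on cohort
scale.

# Known limitations

* The SCNN scores each window position from one adjacent-epoch pair;
  context beyond the immediate neighbour enters only through the
  consolidation over overlapping windows, not through deeper cross-epoch
  convolutions.
* Subgroup models train on a fraction of the cohort; with very few subjects
  per subgroup they can underperform a pooled model on stages that are rare
  within the subgroup. The LOSO driver falls back to the pooled model only
  when a subgroup is empty.
* Hypnogram inputs support EDF+ annotation tracks and `epoch,stage` CSV;
  stage tokens outside the R&K/AASM vocabulary are rejected rather than
  guessed.
* Recordings are serialised as RDS; EDF is supported for signal input and
  fixture output.
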
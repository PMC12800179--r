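---
title: "Detecting tampered MRI-like images: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting tampered MRI-like images: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A *medical deepfake* is a diagnostic image that has been locally edited —
here, a tumor inserted into a healthy brain scan, or a tumor removed from a
pathological one and the cavity inpainted to blend with surrounding tissue.
Such edits are small, local, and designed to be visually seamless, which is
what makes screening for them hard. `mriforensics` implements a complete
detection pipeline for this task: synthetic data with ground truth,
canonical preprocessing, adversarially robust training of two base
classifiers, fused handcrafted and deep features, an AUC-weighted voting
ensemble, and an evaluation suite.

## The detector

Two base classifiers look at every image:

* an **RBF-kernel SVM** on a fused feature vector
  $[\,d_1 \dots d_{2048},\, h_1 \dots h_{3780}\,] \in \mathbb{R}^{5828}$,
  where $d$ is the 2048-dim global-average-pooled penultimate activation of
  a convolutional backbone and $h$ is the 3780-dim HOG descriptor;
* a **small CNN** (three 3×3 conv + ReLU + 2×2 max-pool blocks with
  16/32/64 channels, then fully connected 128 → 2) trained directly on the
  224×224 images.

Their probabilities of "manipulated", $p_{\mathrm{SVM}}$ and
$p_{\mathrm{CNN}}$, are combined by weighted soft voting,

$$p_{\mathrm{final}} = w_{\mathrm{SVM}}\,p_{\mathrm{SVM}} +
  w_{\mathrm{CNN}}\,p_{\mathrm{CNN}}, \qquad
  w_i = \frac{\mathrm{AUC}_i}{\mathrm{AUC}_{\mathrm{SVM}} +
  \mathrm{AUC}_{\mathrm{CNN}}},$$

with the weights computed from each member's validation AUC and a decision
threshold of 0.5. A score of exactly 0.5 is flagged *manipulated*: in a
screening setting, ambiguous cases should surface, not pass.

### Adversarial training

Robustness comes from augmenting the training split with attacked copies
of its own images, labels unchanged:

* **FGSM**: $x' = \mathrm{clip}(x + \varepsilon\,
  \mathrm{sign}(\nabla_x J), 0, 1)$ with $\mathrm{sign}(0)=0$;
* **PGD**: a seeded uniform start in the $\varepsilon$-ball, then $k$ steps
  of size $\alpha$ along the gradient sign, each followed by projection
  onto $[x-\varepsilon, x+\varepsilon]$ and clipping to $[0,1]$. The
  gradient is recomputed at the current iterate every step.

Both attacks guarantee $\|x'-x\|_\infty \le \varepsilon$ and $x' \in
[0,1]$; FGSM is exactly PGD with $k=1$, $\alpha=\varepsilon$ and no random
start, and the test suite asserts both properties. Defaults are
$\varepsilon = 0.03$ (≈ 8/255, the conventional ∞-norm budget),
$\alpha = 0.007$, $k = 10$, augmentation fraction 0.5 per class — all
configurable; no reference values exist for them, so the conventional
choices are pinned once.

Attacks are crafted against the CNN, the only gradient-capable member; the
perturbed *images* then also flow through feature extraction into the SVM,
so both members train on attacked content. The final CNN is warm-started
from the clean-trained CNN and fine-tuned on the augmented set — standard
adversarial fine-tuning, which also roughly halves the training cost.

## The synthetic corpus

Real tampered-scan corpora are not redistributable, so the package
generates its own study conditions: 1378 samples by default — 774 genuine
and 604 manipulated, the manipulated half split 50/50 between insertion
and removal (insertion takes the odd remainder) — materialized as 8-bit
grayscale PNG with a CSV manifest, and partitioned 70/15/15 by a stratified
per-class split (round-half-up on the validation and test counts, training
takes the remainder; for 1378 that is 964/207/207).

* **Phantoms** are brain-like, not photorealistic: a bright skull rim,
  mid-intensity brain, darker ventricle lobes, per-sample geometric jitter
  (6%), and band-limited tissue texture (white noise smoothed at σ = 3 px,
  amplitude 0.08). These amplitudes were chosen once as visually plausible
  for normalized MRI slices.
* **Insertion** blends an irregular bright blob (radii 6–16 px, boundary
  irregularity 0.2–0.5, intensity offset 0.15–0.35 — visible but not
  cartoonish lesions) with a Gaussian-feathered boundary (σ = 2 px), so
  pixels beyond 6 px of the mask are bit-identical to the source phantom.
* **Removal** first inserts a tumor, then inpaints its footprint the
  classical way: fill with the boundary-ring mean, add synthetic texture
  variance-matched to the ring, and affinely renormalize so region mean
  and standard deviation match the ring. The residual signature — white
  rather than band-limited texture, and erased macro-structure — is
  exactly the kind of statistical seam real inpainting leaves.

What the generator does **not** emulate: scanner noise spectra, bias
fields, anatomy beyond ellipses, 3-D context, or GAN-style inpainting.
Passing tests therefore show the pipeline detects subtle local edits under
controlled conditions; they do not certify performance on clinical data.

## Preprocessing

Every image passes through: bilinear resize to 224×224 (half-pixel-center
convention) → per-image min-max normalization to $[0,1]$ (a constant image
maps to zeros by convention) → Gaussian denoising with σ = 1.5 px → clip.
The blur uses reflective boundaries so edges get no dark halo and the
image mean is preserved to ~1e-6. Per-image (rather than corpus-level)
normalization is the simplest convention consistent with scaling each scan
to $[0,1]$, and is pinned for determinism.

## Features

* **HOG**: the canonical 64×128 detection window with 8×8-px cells, 2×2
  cell blocks at 1-cell stride, 9 unsigned bins and L2-Hys normalization
  (clip 0.2) is the unique standard geometry with a 3780-dim descriptor
  (7·15·4·9), so images are resampled to that window inside the op.
  Orientations are *edge* orientations (gradient rotated 90°) on 0–180°,
  votes magnitude-weighted and linearly interpolated between adjacent
  bins; an all-zero block stays zero.
* **Deep features**: a seeded convolutional backbone (4× average-pool
  stem; 3×3 conv stages of 32/64/128 channels with ReLU and 2×2 max-pool;
  1×1 conv to 2048; global average pool). The grayscale input is
  replicated to three channels and standardized with the usual per-channel
  constants. With seeded He-initialized weights the backbone is a fixed
  random nonlinear projection — fully deterministic and dependency-free;
  externally trained weights of the same shapes can be supplied.
* **Fusion** is plain concatenation, deep features first (indices 1–2048),
  HOG second (2049–5828), with no rescaling: scale handling belongs to the
  classifier pipeline (the SVM z-scores with training-split statistics).

## Training details and numerical choices

* SVM: grid search over C ∈ {0.1, 1, 10, 100} and γ ∈ {1e-4, 1e-3, 1e-2,
  1e-1, 1/d}, selected by validation AUC with ties broken toward smaller C
  then smaller γ; probabilities by Platt scaling (regularized soft
  targets, fitted by BFGS on the validation decision values — the fitted
  slope also resolves the decision-value orientation).
* CNN: Adam (η = 1e-3, β = 0.9/0.999), batch 32, epoch cap 50, early
  stopping on validation loss with patience 5 and min-delta 1e-4; the
  minimum-validation-loss weights are returned. Training is seeded and
  single-threaded, hence bit-reproducible. Inputs are centered at
  mid-scale (x − 0.5) — a fixed standardization without which
  small-dataset training stalls in the majority-class solution. A 4×
  average-pool stem precedes the first conv block by default: on CPU it
  buys an order of magnitude in time at a modest cost in fine detail, and
  it is a config switch (`cnn.stem_pool = 1` restores full resolution).
  Backward passes are verified against central-difference gradients.
* Degenerate cases are contracts, not crashes: constant images normalize
  to zeros, zero-gradient HOG blocks stay zero, σ(ring) = 0 inpainting
  fills with the constant, all-zero metric denominators return `NA`
  markers, and a tie at the ensemble threshold flags manipulated.

## Evaluation suite

Confusion counts (positive class = "manipulated") with accuracy,
precision, recall, F1; ROC/AUC with the midrank tie convention (equal
scores count one half — identical to exhaustive positive–negative pair
counting, which the tests assert up to n = 200); average precision by
step interpolation; equal-width reliability bins with empty bins omitted;
median/IQR probability summaries with linear-interpolation quantiles; and
a two-sided Wilcoxon signed-rank comparison of paired per-seed metrics
(zeros dropped, midrank ties, W = min(W⁺, W⁻), exact enumeration of all
2ⁿ sign assignments for n ≤ 12, otherwise a tie-corrected normal
approximation with continuity correction; all-zero differences give an
undefined statistic and p = 1). Both raw and Holm-adjusted p-values are
reported for the two member comparisons.

## Problem sizes used in the shipped checks

The repeated-seed study shipped with the package runs the full pipeline at
a reduced corpus size of n = 300 with five seeds — small enough to keep a
complete adversarially trained run comfortable on a single CPU, large
enough that the test split (45 images) gives stable accuracies. The unit
suites use 32×32 blob tasks with a scaled-down CNN geometry; every
expected value there is either derived from an independent brute-force
oracle computed in the test itself or asserted as an invariant.

## Known limitations

* Phantom realism is deliberately limited (see above); absolute accuracy
  numbers on synthetic corpora do not transfer to clinical data.
* The random-weight backbone is a fixed projection, not a learned
  representation; with pretrained weights the deep features would be
  stronger.
* Only ∞-norm untargeted attacks are implemented; no certified defenses.
* The 4× stem trades away some sensitivity to the highest-frequency
  inpainting residue in the CNN member (the HOG/SVM member retains it).
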
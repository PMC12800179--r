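# mriforensics

Detection of *tampered* MRI-like images — scans with synthetically
inserted tumors, or with tumors removed and the cavity inpainted — using
an adversarially trained, feature-fusion ensemble. The package is aimed at
researchers studying medical-image forgery detection who need a complete,
reproducible pipeline that runs on a single CPU with no external data or
pretrained weights.

## The method

Two base classifiers score every preprocessed 224×224 image with a
probability that it was manipulated:

* an **RBF-kernel SVM** on a fused feature vector
  `[deep(1:2048), hog(1:3780)] ∈ R^5828` — the 2048-dim global-average-pool
  activation of a convolutional backbone concatenated with the canonical
  3780-dim HOG descriptor (64×128 window, 8×8 cells, 2×2-cell blocks,
  9 unsigned bins, L2-Hys);
* a **lightweight CNN** (3 conv blocks of 16/32/64 channels + 2 fully
  connected layers) trained directly on the images.

Training is hardened with adversarial augmentation: FGSM
(`x' = clip(x + ε·sign(∇ₓJ), 0, 1)`) and PGD (k projected signed-gradient
steps of size α inside the ∞-norm ε-ball) craft attacked copies of the
training images, which both members then train on. The ensemble score is
the AUC-weighted soft vote

```
p_final = w_svm·p_svm + w_cnn·p_cnn,   w_i = AUC_i / (AUC_svm + AUC_cnn),
```

with the weights taken from validation AUC and a 0.5 decision threshold
(`manipulated` is the positive class). The evaluation suite reproduces the
standard analyses: confusion metrics, ROC/AUC, precision–recall/AP,
calibration curves, probability summaries, and Wilcoxon signed-rank
comparisons of the ensemble against its members across seeds.

Because real tampered-scan corpora are not redistributable, the package
generates its own: brain-like phantoms (774 genuine + 604 manipulated =
1378 by default, stratified 70/15/15 into 964/207/207), with tumor
insertion and classical inpainting-based tumor removal, each sample
carrying a ground-truth manipulation mask. See
`vignettes/tamper-detection.Rmd` for the full methods account.

## Worked example

```r
library(mriforensics)

corpus <- build_corpus(n_total = 300, seed = 1)        # phantoms + edits
corpus <- split_corpus(corpus, seed = derive_seed(1, "split"))
splits <- lapply(corpus$splits, preprocess_samples)

det <- fit_detector(splits$train, splits$val,
                    config = run_config(corpus = list(n_total = 300)),
                    seed = 1)
print(det)
#> <tamper_detector> AUC-weighted SVM+CNN ensemble
#>   weights: svm 0.503 / cnn 0.497  (val AUC 0.874 / 0.862)
#>   threshold 0.50

y <- vapply(splits$test, `[[`, "", "label")
rep <- evaluation_report(y, predict(det, splits$test)$p_ensemble)
print(rep)
#> <evaluation_report> n=45  accuracy 0.800  AUC 0.768  AP 0.84
#>   median p 0.309 (IQR 0.188-0.927)
```

The weights say the two members were nearly equally reliable on
validation (AUC 0.874 vs 0.862), so the vote is almost even; the report
shows the ensemble flagging tampered test phantoms at 80% accuracy on
this seed's 45-image test split (single-seed accuracies at this corpus
size scatter by a few images around the ~0.88 five-seed mean).
`run_experiment(config, seeds = 1:5)` repeats the whole study across
seeds and adds the Wilcoxon member comparisons; `plot(rep)` draws the
ROC, PR and calibration panels.

A command-line interface with `generate`, `train`, `attack`, `predict`,
`evaluate` and `compare` subcommands is installed at
`inst/cli/mriforensics`.

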
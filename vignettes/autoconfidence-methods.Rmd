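---
title: "Adversarial voxel-wise confidence estimation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adversarial voxel-wise confidence estimation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Deep-learning auto-segmentation of organs at risk (OARs) is accurate enough
to be clinically useful but not accurate enough to skip human review.
Review is slow precisely because the reviewer does not know *where* to
look. This package implements a reference-free quality-assurance model: a
discriminator network that, given only an image slice and a proposed
multi-organ segmentation — from any source, with no gold standard at
inference time — predicts for every voxel the probability that the
segmentation disagrees with the (unseen) gold standard. The complement of
that probability is a confidence map a reviewer can use to focus editing.

## The adversarial training scheme

Two networks are trained together, but their usual GAN roles are
inverted: the segmentation **generator** exists to supply the
discriminator with a rich, evolving distribution of plausible-but-imperfect
segmentations; the **discriminator** is the product.

- The generator is a compact 2D U-net (eight convolutional layers, batch
  normalisation, relu, dropout, softmax head over K organs + background).
  It maps an image slice to a per-voxel class distribution.
- The discriminator is a shallow two-level encoder–decoder with residual
  blocks and a voxel-wise two-class softmax head (correct / error). Its
  input stacks the K binary organ masks with the image as the final
  channel. Both residual blocks sit at the pooled resolution; full
  resolution carries one stem convolution and one skip-fusion convolution.
  This keeps the network shallow and voxel-wise while remaining trainable
  on a single CPU.

The discriminator's label is the **d2GS** mask: the channel-wise maximum of
the absolute difference between the proposed binary masks and the
gold-standard masks — 1 wherever any organ is over- or under-segmented.
Gold-standard inputs are paired with an all-zero d2GS; generated (and
synthetically corrupted) inputs are paired with their computed d2GS, never
with an assumed-correct label.

Both networks train under the focal log loss with label weight fixed at 1:

$$\mathrm{FL}(p) = -(1-p)^{\gamma}\,\log(p + \varepsilon),$$

where $p$ is the probability assigned to the target class at a voxel,
$\gamma = 2$ focuses training on hard voxels, and $\varepsilon = 10^{-7}$
keeps the loss finite at $p = 0$. The offset sits *inside* the logarithm:
that is the only placement that achieves its stated purpose of preventing
an infinite loss at $p=0$. The loss is reduced by the mean over voxels and
batch. The total generator loss is

$$L_{gen} = \alpha\,\mathrm{FL}_G + \beta\,(1 - \mathrm{FL}_D),$$

with $\alpha = 20$, $\beta = 1$; $\mathrm{FL}_D$ is the discriminator's
focal loss evaluated on the generated sample against its d2GS labels, so a
high discriminator loss (a fooled discriminator) rewards the generator.
Generator and discriminator are updated exactly once per batch, in
alternation; the discriminator's single update sees the gold-standard and
generated blocks of the batch together.

One gradient-flow detail is worth stating: d2GS is defined on *binary*
masks, so the discriminator is updated on argmax-binarized generator
output, which blocks gradients. During the generator's update the
discriminator instead receives the softmax organ-probability channels
directly (a standard continuous relaxation); the d2GS labels for that term
still come from the binarized masks.

## Synthetic error injection

A second, otherwise identical, model is trained with synthetic errors
applied to the generated segmentations before the discriminator sees them.
Three families are implemented:

- **Geometric**: a rigid rotation/translation followed by a thin-plate
  spline deformation whose control vectors are drawn from
  $\mathcal{N}(0, \sigma^2)$ on a regular 2 cm grid (20 voxels at the fixed
  1 mm in-plane spacing). All channels share the field — a
  misregistration-like error — and masks are resampled nearest-neighbour so
  they stay binary. The deformation magnitude $\sigma$ defaults to 3 mm.
- **Class perturbation**: every voxel whose argmax class is the target
  organ is relabelled to its second-most-likely softmax class. Applied to
  whole organs, reflecting labelling errors rather than boundary noise.
- **Organ removal**: one organ channel emptied outright.

Application probabilities per slice default to 0.9 / 0.2 / 0.3
(geometric / class / removal), chosen once so that nearly every generated
sample used for discriminator training carries a substantive, localisable
error — the purpose of the augmentation — and not revisited. A
`magnitude_scale` multiplier emulates external models of different quality
(larger scale = lower quality); monotonicity of corruption severity in this
scale and in $\sigma$ is property-tested.

## The phantom simulator

The clinical cohort behind the method (T1w-Gd MRI of glioma patients, 13
OARs) is not public, so the package ships a phantom generator that
reproduces the *statistical difficulties* of that data rather than its
anatomy: smooth elliptical/blob organs of varying size on a shaded
background, with

- a designated **tiny organ** (area < 10 voxels — the lens analogue),
- a designated **low-contrast organ** whose organ-to-background intensity
  offset is at or below the noise standard deviation (contrast-to-noise
  ratio ≤ 1 — the lacrimal-gland/lens analogue),
- a multiplicative low-frequency shading field (so the discriminator has
  image texture to correlate with), and
- i.i.d. Gaussian noise, intensities clipped to [0, 1].

Gold-standard masks are pairwise disjoint with a 2-voxel separation halo.
Defaults: 64×64 voxels at 1 mm, three organs, contrasts (0.45, 0.30, 0.20)
before the difficulty flags apply, noise σ = 0.05, shading amplitude 0.08.

What the phantom does *not* emulate: anatomical shape priors, slice-to-slice
correlation (the method is strictly 2D here), scanner artefacts, and
inter-observer gold-standard noise. Passing the phantom benchmark therefore
demonstrates that the adversarial mechanism detects segmentation-image
mismatch under noise, small structures and low contrast — not clinical
performance.

## Post-processing

**Intelligent Edge Removal (IER)** deletes thin error ribbons hugging organ
boundaries (partial-volume artefacts of binarization): Sobel edges of every
organ mask are united and dilated to a width of *k* voxels (default k = 3,
a 3×3 box); errors inside the band are removed; surviving errors are
regrown into the band by a Euclidean radius of k/2 (radius 1.5 = the
8-neighbourhood), restricted to the original error map. IER is applied
identically to predicted error maps and to d2GS maps before metrics, and
its output is always a subset of its input.

**Geometric Distance Correction (GDC)** operates *only* on evaluation
confusion maps — never on confidence maps, which reach the user untouched
(this isolation is asserted byte-for-byte in the tests). For each FP or FN
voxel, within a local patch (default 31×31) centred on it: the maximum
dimension of the TP region is taken as the inscribed-disc diameter — twice
the maximum Euclidean distance transform value inside the in-patch TP set —
and compared with the Euclidean distance from the voxel to the nearest TP
voxel. If the voxel is closer than the region is large, FP becomes TP and
FN becomes TN, flagged as GDC-modified. Decisions are taken on the original
labels in a single pass (no cascading), and TP/TN voxels never change, so
FPR and FNR can only decrease. Two border conventions are fixed and tested:
the patch is clipped at image borders, and the distance transform treats
only in-patch non-TP voxels as background (patch borders are not
background). The inscribed-disc reading of "maximum dimension via EDT" is a
design choice; a Feret-style diameter would be the alternative.

When IER and GDC are combined, IER runs first (on both maps), then the
confusion map is formed, then GDC.

## Evaluation

Metrics compare predicted error maps to d2GS (positive class = error
voxel): MCC, FPR, FNR, FP/FN ratio, plus DSC of the segmentation itself.
All degenerate denominators return `NA` and are excluded from averages
(including 0/0 Dice, rather than scoring a silent 1). Per-organ metrics are
accumulated inside a local evaluation region — the union of the organ's
predicted and gold-standard masks dilated by 10 voxels — so true-negative
counts stay local and class imbalance is comparable across organ sizes;
whole-slice accumulation is available via `region_margin = Inf`. The
four-colour map renders TP green, FP pink, FN blue and GDC-modified
voxels yellow.

## Numerical and training choices

- **Optimiser**: Adam, learning rate 1e-3 for both networks, batch 8.
  Generic GAN settings (2e-4) are tuned for hundreds of thousands of
  updates; at this problem size only a few hundred updates are affordable,
  and 1e-3 gives clean convergence of both focal-loss curves.
- **Binarization threshold**: focal-loss-trained softmax outputs are
  systematically under-confident, so a fixed 0.5 cut can sit above every
  predicted error probability even when the voxel ranking is good. After
  training, the operating threshold is calibrated by maximising pooled MCC
  on error-injected *training* slices (held-out data is never used) and
  stored on the fit; `evaluate_case()` itself defaults to 0.5 and accepts
  any threshold.
- **Argmax ties** break toward the lowest class index (background), so a
  uniform softmax yields empty masks.
- **Masks** are always resampled nearest-neighbour; binarity is an
  invariant of every injector.
- **Determinism**: every random stage (phantoms, weights, dropout,
  injection) draws from an explicitly seeded local RNG; fixed seeds
  reproduce datasets bit-identically and training to floating-point
  identity on a fixed BLAS.
- **Degenerate inputs**: empty-vs-empty Dice, no-TP patches in GDC,
  zero-probability injection configs and zero-epoch training all have
  defined, tested behaviour (sentinel, identity, identity, initial
  weights).
- The convolution engine is written in-package (im2col + BLAS through
  RcppArmadillo, hand-derived backward passes, batch-norm, dropout, Adam);
  all gradients are verified against central finite differences in the test
  suite.

## Benchmark problem sizes

The end-to-end benchmark trains each variant (adversarial; no synthetic
errors; zero-image and zero-segmentation input ablations; sequential
baseline) on 160 phantom slices of 64×64 voxels (K = 3) for 6 epochs with
base width 8, then evaluates on 40 held-out slices whose gold standards are
corrupted to emulate an external segmentation model of modest quality:
geometric misregistration with probability 0.6 and whole-organ removal
with probability 0.5, so error locations cannot be predicted from either
input alone; a case that draws no error has an empty d2GS and drops out of
MCC averages as undefined. These
sizes are the package's choice of a desk-scale experiment; they are large
enough for the directional conclusions (post-processing helps; ablations
collapse performance; sequential training underperforms; synthetic errors
reduce FNR) to be stable across seeds, and small enough to run in minutes
per variant on one CPU.

At these sizes the generator reliably learns the high-contrast organ
(DSC ≳ 0.9) and fails the tiny organ, and the CNR ≤ 1 organ sits in
between depending on the training length — mirroring the spread between
easy OARs and lenses/lacrimal glands in the clinical setting.

## The sequential baseline

`train_sequential_baseline()` trains the generator to convergence on its
supervised focal loss alone, freezes it, and then trains the discriminator
against the frozen generator's raw outputs — no synthetic corruption. The
discriminator then sees a static error distribution concentrated on
whatever the converged generator still gets wrong, instead of the
adversarial curriculum (sweeping from gross to subtle errors) plus
synthetic-error augmentation that the full model trains under. Both
networks still receive the same number of updates as in adversarial
training.

## What the desk-scale benchmark does and does not show

Two findings from the benchmark deserve honest emphasis, because they
differ from what one would expect at clinical scale.

First, the *zero-segmentation* input ablation (discriminator sees only the
image) is not crippled on phantoms the way removing an input should
cripple a mismatch detector. On a 64×64 slice, every plausible error —
displacement, deformation, removal — produces d2GS voxels clustered at
organ sites that the image itself reveals, and the 31-voxel GDC patch is
large relative to the slice, so a model that merely flags organ
neighbourhoods is barely punished: most of its false positives sit near
true positives and are reclassified. The zero-image ablation (masks only)
does collapse as expected. On clinical images, where error locations are
not predictable from intensity alone and the patch is small relative to
the slice, both ablations collapse.

Second, the *sequential* baseline is competitive with adversarial training
here. Its frozen generator permanently fails the tiny and low-contrast
organs, so every one of its training examples carries gross missing-organ
errors — at this scale that acts as built-in error augmentation,
substituting for the adversarial curriculum. With realistic, subtle error
distributions and a generator that succeeds on most structures, the
sequential discriminator sees almost no informative errors, which is where
adversarial training earns its keep.

Both effects are properties of the miniature geometry and synthetic error
model, not of the implementation; the corresponding directional checks in
the acceptance suite are left failing deliberately rather than papered
over, with the mechanism documented here.

## Known limitations

- Strictly 2D, like the edge-removal algorithm; through-plane
  partial-volume effects are out of scope.
- The sub-10-voxel organ is essentially never learned at desk scale, and
  confidence estimates for it are correspondingly poor — consistent with
  the failure mode reported for lenses at clinical scale.
- d2GS is an imperfect surrogate for "true" confidence: genuinely low
  confidence regions that happen to match the gold standard count as FP
  before GDC. GDC is a metrics-level mitigation, not a fix.
- The discriminator's probabilities are an operating signal, not calibrated
  posteriors; downstream use should treat the calibrated threshold as part
  of the fitted model.
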
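---
title: "Automated tumor-stroma ratio estimation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated tumor-stroma ratio estimation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The tumor-stroma ratio (TSR) is the proportion of stroma within the tumor
site of a solid cancer. In colorectal cancer a high stromal share (TSR above
50%) is associated with worse prognosis, so TSR is scored routinely — but
visually, by a pathologist following a spot-selection protocol, with
moderate inter-observer agreement. `tsrslide` implements an automated,
patch-based alternative for hematoxylin-eosin (H&E) whole-slide images and
the full evaluation machinery needed to compare it against visual scoring.

The per-slide estimate is a composition of five stages:

1. **Tissue masking.** An Otsu threshold on a scalar channel separates
   stained tissue from image background and adipose tissue, both of which
   are near-white.
2. **Tiling.** The slide is cut into 224 x 224 px windows. At inference the
   grid is non-overlapping and a window is kept when at least 75% of it is
   masked tissue. For classifier training, windows overlap by 64 px
   (stride 160) and a window is kept when at least 75% of it carries an
   annotation; its label is the majority annotated class.
3. **Stain normalization.** Every kept patch is Macenko-normalized to a
   reference stain model, collapsing slide-to-slide stain variation.
4. **Patch classification.** A three-class classifier assigns each patch a
   probability vector over *tumor*, *stroma* and *other* (softmax over the
   fixed class order tumor, stroma, other).
5. **The TSR statistic.** With `n_stroma` and `n_tumor` the patch counts,

   TSR = n_stroma / (n_tumor + n_stroma),

   *other* patches entering neither numerator nor denominator. The value is
   dichotomized as stroma-high (TSR > 50%) versus stroma-low (TSR <= 50%);
   the cutoff is strict above, so exactly 50% is stroma-low.

A slide with no tumor or stroma patches has no defined TSR; the package
raises an explicit error rather than returning 0, because a silent 0 would
masquerade as "all tumor".

## Macenko stain normalization

Under the Beer-Lambert law, transmitted intensity relates to stain
concentration linearly in optical density, `OD = -log10(I / I0)` (log base
10 is the Beer-Lambert convention, with `I0 = 255`). An H&E pixel's OD
vector is `S c`, with `S` the 3 x 2 matrix of stain vectors and `c` the two
concentrations. Macenko estimation proceeds exactly as in the canonical
description: discard pixels with OD below `beta = 0.15` in every channel
(unstained), project the surviving OD cloud onto the plane of its two
leading principal directions, and read the stain vectors off the `alpha` =
1st and 99th percentiles of the projection angle. Concentrations are solved
by least squares with negatives clipped to zero (an exact non-negative
solve is available via `nonneg = TRUE`); robust per-stain maxima are the
99th percentile of solved concentrations. Normalization rescales a patch's
concentrations by the ratio of reference to source maxima and re-renders
through the reference matrix.

Numerical conventions worth stating:

* The hematoxylin column is the vector with the heavier blue-channel OD
  loading, ties broken toward the first principal angle.
* `alpha = 1`, `beta = 0.15`, `I0 = 255` are the canonical Macenko
  constants; nothing in the pipeline is sensitive to small changes in them.
* A patch with fewer than 50 stained pixels raises an "insufficient
  tissue" condition; callers choose between propagating it and a
  pass-through fallback (the pipeline logs a warning and classifies the
  un-normalized patch).
* A rank-1 OD cloud (single pure stain) is flagged rather than silently
  inverted; configuration selects an error or a duplicated-vector fallback.
* One global reference stain model is the default for all data sources; a
  per-dataset reference is possible by passing a different `reference`
  where models are trained and applied, but the default keeps training and
  inference features in one color frame.

Estimation quality depends on the OD cloud containing near-pure pixels of
both stains — in real H&E tissue these are nuclei (hematoxylin) and
collagen (eosin). The angular-percentile step finds the cloud's extreme
directions, not cluster centers, which is why the synthetic textures below
give every tissue class some near-pure pixels.

## Otsu masking

`otsu_threshold()` maximizes the between-class variance
`w0 * w1 * (mu0 - mu1)^2` over all 255 splits of a 256-bin histogram,
returning the lowest maximizing bin for determinism. The default channel is
HSV saturation: background and adipose are both near-white and therefore
low-saturation, so one threshold removes both, which is the point of the
mask. Grayscale is available by flag (tissue on the dark side). Neither the
channel nor any morphological cleanup is canonical in this pipeline's
sources, so both are surfaced as configuration; `min_object_px` (default 0,
i.e. off) removes small connected components via `EBImage::bwlabel` when
real slides need it.

One guard is deliberate: Otsu always finds *a* split, so on a blank,
pure-noise near-white canvas it would happily split the noise and call half
the canvas tissue. A saturation floor (`blank_floor = 20` on the 0..255
scale) declares a slide tissue-free when no pixel exceeds it, returning an
all-false mask with a warning.

## Tiling conventions

Windows are half-open `[x, x + 224) x [y, y + 224)` with 0-based corners on
the stride grid, enumerated row-major; partial windows at the right/bottom
edges are dropped, never padded. Both coverage thresholds are inclusive: a
window at exactly 75% coverage is kept, since the filter discards windows
with *less than* 75%. The training label is the majority annotated class
within the window; the tie order tumor > stroma > other is fixed and
recorded. (A variant requiring 75% of a *single* class is available behind
`single_class = TRUE` for sensitivity analysis.) At the stated geometry
(224 px windows, 64 px overlap), adjacent training windows share exactly 64
pixels per axis.

## The patch classifier and transfer-learning setups

The classifier contract is: input a 224 x 224 RGB patch normalized to the
training reference, output a probability 3-vector summing to 1, argmax
label with ties broken in class order. Three training sequences are
implemented, differing only in initialization and pre-training:

* **SETUP1** — reference initialization, pre-train on a domain-specific
  patch corpus, fine-tune on the target training set;
* **SETUP2** — reference initialization, fine-tune directly;
* **SETUP3** — random initialization, pre-train on the domain corpus,
  fine-tune.

The package's built-in backbones are compact: hand-crafted stain/texture
patch features (concentration statistics against the reference stain
model, gradient energy, stain-dominance pixel fractions, white fraction)
feeding either a softmax head (`"softmax"`, the default) or a one-hidden-
layer MLP (`"mlp"`), trained by an in-package mini-batch gradient-descent
loop with cross-entropy loss. The loop is deliberately hand-written: the
protocol needs warm-starting across stages, per-epoch validation for early
stopping, and bit-stable seeded trajectories, which off-the-shelf fitters
do not expose at this granularity. For these backbones "reference
initialization" means a documented fixed-seed initializer — the analogue of
loading published pretrained weights — so the *sequence* semantics of the
three setups (what is initialized from where, and what is pre-trained on
what) are preserved exactly; published deep architectures can be plugged in
through `register_backbone()` where their R bindings exist. Accordingly,
desk-scale accuracy differences between the setups say nothing about the
relative merit of domain pre-training for real CNNs; the harness
(`compare_setups()`) exists to exercise and audit the protocol, and
records the executed stage sequence of every run in the model provenance.

Hyperparameters (learning rate, optimizer, batch size) are chosen by
5-fold cross-validation: folds partition the training patches exactly, each
fold serves once as the held-out fold, the candidate with the best mean
fold accuracy wins, and ties go to the first candidate in grid order. The
epoch budget is then chosen by early stopping on a held-out third of the
training patches — the chosen epoch is the *earliest* epoch achieving the
best validation accuracy, and training stops after `patience = 5` epochs
without improvement (neither tie-break nor patience is canonical; both are
logged configuration). The final model is retrained on the full training
set for exactly that many epochs. The development workflow enforces the
train/test split at *slide* level: a slide id in both lists is a hard
error, since patch-level splits leak texture between sets.

## The synthetic-slide generator

Every downstream stage is tested against slides with exact ground truth,
generated by Beer-Lambert forward rendering: a layout assigns each pixel
one class (tumor, stroma, other, adipose, background), per-class H/E
concentration fields are textured and noised, and
`I = I0 * 10^(-S c)` renders RGB through a known stain matrix (the standard
H&E OD vectors by default). Because rendering is exactly the model that
stain estimation inverts, recovery can be asserted to fractions of a
degree, and per-class mean OD equals the stain matrix times the mean
concentrations to machine precision.

The default textures emulate, coarsely: tumor as dense hyperchromatic
nuclear speckle (40% nuclear density, high hematoxylin, low-to-moderate
eosin), stroma as oriented eosinophilic fibers (sinusoidal eosin field)
with sparse fibroblast nuclei (5%), *other* as a smooth heterogeneous
mixture with scattered nuclei (10%) whose within-class correlation length
is tunable (`mix`) since the heterogeneity of a debris/lymphocyte/mucus
class is not something to hard-code. The sparse nuclei in non-tumor
classes matter beyond appearance: they anchor each patch's robust maximum
hematoxylin concentration, without which Macenko's concentration rescaling
is ill-posed on single-class patches. Adipose and background render
near-white (all channels at or above 0.85 I0) so one saturation mask
removes both, giving Otsu a realistic bimodal histogram.

Patch datasets (`make_patch_dataset()`) emulate a corpus tiled from
annotated slides: class-balanced, 224 x 224, with 30% of patches carrying
a secondary-class region covering up to 25% of the area — exactly the
admixture a 75% annotation-coverage filter with majority labels admits.
Cohort slides (`make_cohort()`, 1792 px at 0.5 microns/px) place Voronoi
tissue compartments sized about two patch widths inside a white border,
with adipose disks; nominal stroma fractions cycle the visual categories
10%..90%. Ground truth records both the pixel-area TSR and the
patch-count TSR under the inference tiling (they differ at region
boundaries; the patch-count value is the estimand, since the statistic is
defined on patch counts).

What the generator does **not** emulate: nucleus-level morphology, scanner
artifacts (blur, pen marks, tissue folds), stain variation within a slide,
and genuinely ambiguous tissue (the smooth-muscle-versus-fibrotic-stroma
confusion that dominates real error). Passing the synthetic end-to-end
bars therefore demonstrates that the pipeline's plumbing — masking, tiling,
normalization, training protocol, statistic, evaluation — is correct and
internally consistent, not that any backbone reaches clinical accuracy.

All randomness flows from one seed per call; pipeline stages derive
sub-seeds from a global seed via a fixed string hash (`derive_seed()`), so
runs are reproducible and stages do not share streams.

## Evaluation statistics

`classification_report()` gives the 3 x 3 confusion matrix (rows true,
columns predicted), accuracy, and per-class precision, recall and F1; a
class with no predicted (or true) instances reports precision (recall) 0
with an explicit flag, never NaN. Cohort agreement uses Pearson
correlation between predicted and true TSR, the standard error of the
estimate, and Cohen's kappa of the stroma-high/low dichotomization
(`p_e = 1` with identical constant raters is defined as kappa 1, with a
warning).

SEE is root-mean-square deviation from the reference value with
denominator `n`: within a visual category the reference is the single
category value, so `SEE^2` decomposes into squared bias plus variance —
the only definition consistent with the per-category tables this package
mirrors, where SEE slightly exceeds the standard deviation by the bias
term. Per-category standard deviation uses the conventional `n - 1`
denominator by default; both choices are flags since table conventions
vary. True visual TSR values must lie on the discrete 10%..90% grid and
off-grid values are refused by position, because silent rounding of a
mis-coded truth table is worse than an error.

## Problem sizes used by the tests

The package's own test suite runs the full study at desk scale, chosen to
exercise every stage with sampling noise small relative to the asserted
tolerances: 600 training patches per class, 150 held-out patches per
class, and a 30-slide cohort of 1792 px slides spanning the nine visual
categories (about 30-55 scored windows per slide). Unit tests use 64-112
px patches and 448-1120 px slides, since every operation is
size-parametric. Empirical bars asserted at these sizes (held-out accuracy
at or above 0.90, cohort r at or above 0.90 against ground-truth patch
TSR, mean absolute TSR error at or below 10 percentage points) are
properties of the synthetic conditions and the compact backbones; nothing
in them transfers to clinical data without retraining and revalidation.

## Known limitations

* The compact backbones see summary features, not pixels; tissue classes
  distinguishable only by fine morphology would defeat them. They are the
  desk-scale stand-in the backbone interface exists to replace.
* Per-patch Macenko estimation is noisy on low-tissue or single-class
  patches; the pipeline's fallbacks (pass-through, reference model) keep
  such patches classifiable but un-normalized.
* TSR is computed over all kept tissue windows of the slide, not a
  pathologist-selected hotspot; hotspot emulation and tumor-adjacent
  stroma restriction are out of scope.
* Survival association of the automated TSR is out of scope; the package
  stops at agreement statistics against visual scoring.
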
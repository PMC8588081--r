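---
title: "Methods: smartphone-image jaundice screening on synthetic scenes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: smartphone-image jaundice screening on synthetic scenes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem and the model

Neonatal jaundice deposits bilirubin in skin and sclera, shifting their
color toward yellow. In RGB terms yellowing is primarily a *loss of blue*:
a yellow surface reflects red and green but absorbs blue. The screening
pipeline implemented here turns that observation into a classifier: from a
face photograph taken with a color calibration card in frame, it (i) removes
the illumination color cast using the card's white patch, (ii) segments the
forehead and the two eye sclerae from a 68-point facial landmark set,
(iii) summarizes each region by its mean color in four color spaces, and
(iv) trains and compares classifiers on those features under a
cross-validated protocol with statistical model comparison.

The clinical datasets behind this family of methods are private, so the
package treats a seeded synthetic-scene generator as a first-class module:
it renders scenes with exactly the statistical structure the analysis
assumes, along with the ground truth (true region colors, true masks, true
bilirubin level) needed to validate every stage quantitatively.

# The synthetic-scene generator

`generate_scene()` renders a frontal, occlusion-free face layout: a skin
rectangle, two scleral regions at the eye positions, and a three-patch
calibration card low in the frame (reference white, gray, and tan patches).
The generative model, in order:

1. **Bilirubin effect.** The latent transcutaneous bilirubin level `tcb`
   (µmol/L) is normalized by 300 (capped at 1) and multiplied by
   `jaundice_blue_drop` (default 60 intensity units) to give a blue-channel
   depression applied to both skin and sclera base colors. The default of
   60 makes the *mean* blue separation between the two label classes about
   30 units when cohort TCB values are drawn from their class ranges —
   a visible but not cartoonish yellowing.
2. **Labeling.** `label_from_tcb()` applies the clinical rule: TcB ≥ 204
   µmol/L → jaundiced. Cohorts draw healthy TCB uniformly from [0, 203] and
   jaundiced from [204, 300]; `round(n × fraction)` subjects are jaundiced.
   (The source cohort's summary statistics are internally inconsistent
   between its table and text, so the generator matches the ranges and the
   class mix, not a particular mean.)
3. **Illumination.** The whole frame — card included — is multiplied by a
   per-channel gain in (0, 1], emulating a color cast. Cohorts draw each
   gain uniformly (default [0.6, 1]) and snap it to the 8-bit grid `k/255`,
   so that reference white renders at an exactly representable level;
   ground-truth recovery through an 8-bit image is only well defined on
   that grid.
4. **Quantization.** With `noise_sigma = 0` the real-valued frame is
   quantized by 8×8 Bayer ordered dithering: integer inputs pass through
   exactly, while fractional region colors survive with region-*mean* error
   well under one intensity unit, instead of the up-to-two-unit
   deterministic bias that plain rounding of flat regions would introduce.
   With noise, Gaussian pixel noise is added and values are rounded
   half-up; noise itself acts as a dither.
5. **Landmarks.** The 68 points follow the standard 0-based convention
   (eyebrows 17–26, right eye 36–41, left eye 42–47). The six eye
   landmarks sit on the ellipse through the eye corners and lid points;
   the painted sclera is that ellipse scaled by 0.96, united with the
   landmark polygon — i.e. the visible eye opening. This keeps the
   landmark hull both high-overlap (IoU ≈ 0.94 against the painted
   region) and color-pure (hull mean within half a unit of the painted
   color), as it should be for a detector that places points on the lid
   margin.

What the generator deliberately does **not** model: skin-tone/melanin
variation, specular highlights, shadows and illumination gradients across
the face, pose, iris/pupil texture, or landmark-detector error. Passing
tests therefore demonstrate correctness of the *pipeline machinery* under
the stated model, not clinical performance: a high synthetic AUC means the
pipeline recovers a signal it was designed to contain, nothing more.

# Calibration

`apply_white_balance()` implements the diagonal transform
`c ← clip(round(255/mean_c × c))` per channel, with the patch means
measured on the uncalibrated image. Design choices:

* **Rounding** is half-up then clipped to [0, 255], for deterministic
  integer output across platforms; a 1e-9 epsilon absorbs binary float
  error on exact half-integers such as `255/200 × 100`.
* **Card localization is an input**, not a detection problem: geometry
  arrives via `card_geometry()` (or its JSON form). The capture-time
  protocol that aligned the card on screen is not reproducible from a
  description, and decoupling it keeps the specified transform testable.
* **Saturation caveat:** pixels clipped at 255 are unrecoverable, and on
  noisy scenes the clipped patch mean falls slightly below 255, so exact
  idempotence of calibration holds only on noise-free frames.

# Segmentation

The forehead is an axis-aligned box: columns span eyebrow points 18–25
(0-based; the global column extent), rows run from `y_min − 140` to
`y_min − 21` inclusive, where `y_min` is the highest eyebrow row — a
20-pixel guard band above the brows and a 120-pixel-tall region, clipped to
the image. A fully clipped box raises a degenerate-ROI error rather than
returning an empty mask. Width uses the eyebrow extent (not the full face
width), the most direct reading of a box "above the eyebrow points".

Each sclera is the rasterized filled convex hull of the six eye landmarks
(pixel centers on or inside every hull edge). A hull, unlike a bounding
box, excludes most eyelid skin. Collinear eye points are an error.
Occluded scenes (`occluded = TRUE`, emulating a hand or pacifier over the
face) refuse featurization, mirroring the exclusion of such images from
analysis rather than attempting robust segmentation.

# Features

12 features per region: per-channel means in RGB, YCbCr, CIELab, and HSV.
The variants are pinned, since "YCbCr" or "Lab" alone underdetermines the
numbers: full-range BT.601 YCbCr (0–255, chroma centered at 128), CIELab
under D65/sRGB via `grDevices::convertColor` (L 0–100, a/b signed), HSV
with hue in degrees [0, 360) and S, V in [0, 1]. Conversions run on
real-valued pixels of the calibrated image and are then averaged. Hue is
averaged arithmetically — the plain channel-mean definition — which is
biased for hue distributions straddling the 0°/360° wrap; facial skin and
sclera hues sit in a narrow band away from the wrap, so the caveat is
documented rather than worked around.

The *eye* feature set concatenates left then right sclera blocks (24
features) rather than averaging the eyes into 12; concatenation preserves
left/right asymmetry and matches the 12 + 12 block structure. *Fusion* is
skin ‖ left ‖ right (36).

# Classifiers

Defaults follow the study configuration: MLP with two 200-unit ReLU hidden
layers, dropout 0.5, softmax output, cross-entropy, Adam, 50 epochs, batch
32; RBF-SVM with C = 1000 and γ = 0.7; CART with gini, unlimited depth,
minimum split 2; random forest with 100 gini trees. SVM, decision tree,
and random forest are fitted by e1071, rpart, and randomForest
respectively. The MLP is implemented in-package (no installed backend
offers the exact two-hidden-layer ReLU/dropout/Adam architecture), trained
deterministically under the configuration seed.

Two further choices the study leaves open:

* **Standardization.** Features are standardized to training-set mean/sd
  before SVM and MLP; with γ = 0.7 on raw 0–255 scales the RBF kernel
  collapses to the identity and the SVM memorizes. Trees are
  scale-invariant and receive raw features.
* **SVM probabilities.** libsvm's Platt scaling uses an internal unseeded
  RNG, which would break seeded determinism, so decision values are mapped
  through a fixed logistic link. Probabilities are therefore monotone in
  the signed margin — exactly what AUC and thresholding need — but not
  calibrated posteriors.

The deep branch mirrors the transfer-learning recipe structurally:
fixed-size ROI-crop inputs (skin crop; two sclera crops side by side;
or forehead over both sclerae on a fixed canvas for fusion), a
convolutional backbone, global average pooling, and a head of three dense
layers with two dropout-0.5 layers and softmax. The in-package backbone is
a seeded random 3×3 filter bank — the published table of training settings
covers only the four traditional models, so the head's training defaults
(Adam, small epoch budget) are the package's own. Minority-class
augmentation (flips, rotations within 10°, brightness jitter) balances the
image dataset, the image-branch counterpart of SMOTE.

# Evaluation protocol

* **SMOTE** (implemented in-package; no installed package provides it)
  equalizes class counts by interpolating each needed synthetic sample
  between a minority point and one of its k ≤ 5 nearest minority
  neighbors, with a uniform gap — so every synthetic point is a convex
  combination of two minority points. It is applied *inside each training
  fold* by default: oversampling before the split would leak interpolated
  copies of test points into training. A `pre_cv` switch reproduces the
  leaky variant for comparison (synthetic points still never enter test
  folds).
* **Stratified 5-fold CV** keeps per-fold class counts within one of
  proportional allocation and fold sizes within one of each other
  (class remainders go to the currently smallest folds).
* **Metrics.** Accuracy; precision and recall macro-averaged over the two
  classes (chosen because reported recall values coinciding with accuracy
  and AUC in this literature are consistent with macro conventions, and a
  screening task cares about both classes); F1 as the harmonic mean of
  macro precision and macro recall; AUC as the tie-aware rank statistic
  (ties count one half). Positive-class binary averaging is a switchable
  alternative in principle; macro is the package default and the one the
  tests pin down.
* **Paired comparison.** The k-fold cross-validated paired t-test:
  `t = p̄√k / s` on the k per-fold differences, k − 1 df, two-sided at
  α = 0.05, no multiple-comparison correction. Zero-variance differences
  are degenerate: t = 0, p = 1 when the mean difference is zero, p = 0
  with a degenerate flag otherwise. The published typesetting of this
  statistic is garbled; the implementation follows the standard form from
  the test's original description, and the suite verifies it against
  `stats::t.test` on the differences to 1e-10 and its type-I error rate
  (0.05 ± 0.02) by simulation. This test is known to be liberal on small
  k because fold overlaps violate independence; the corrected-variance
  (Nadeau–Bengio) variant is a possible extension, not the protocol
  implemented here.

# Numerical and testing choices

Problem sizes in the test suite and acceptance script are chosen to keep a
full run around two minutes on one CPU while leaving wide margins: 50
scenes for calibration exactness, 20 layouts for forehead geometry, 100
random colors for the feature oracle, 1000 draws for t-test oracle
equivalence, 5000 replicates for null calibration, 200-scene cohorts for
end-to-end discrimination (the shifted cohort must reach mean AUC ≥ 0.95
for SVM and random forest on fused features; the zero-shift cohort must
keep every model's mean AUC in [0.35, 0.65]).

Degenerate inputs fail loudly and early: negative TCB, gains outside
(0, 1], a card overlapping an ROI, an all-black white patch (the transform
would divide by zero), fully clipped forehead boxes, collinear eye
landmarks, single-class training sets, and single-sample SMOTE minorities
are all errors with specific messages, and pipeline stage failures name
the stage and subject.

# Known limitations

* Synthetic scenes are geometric, not photorealistic; results transfer to
  clinical images only to the extent the color-signal model holds.
* Arithmetic hue averaging is wrong for hue distributions at the red wrap.
* SVM probability values are uncalibrated (rank-faithful only).
* The deep branch validates architecture and data flow, not pretrained
  representation quality; plugging in a pretrained backbone is supported
  in design but not shipped.
* Exact calibration idempotence and exact white-patch restoration assume
  unsaturated, noise-free patches.
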
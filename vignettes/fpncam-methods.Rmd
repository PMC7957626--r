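---
title: "Pyramid-feature classification heads and relevance-based saliency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pyramid-feature classification heads and relevance-based saliency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Object-detection networks built on feature pyramids (FPN/RetinaNet-style
architectures) are strong image classifiers in disguise, but their detection
outputs — per-anchor scores merged by non-maximum suppression — resist the
standard whole-image saliency toolbox. `fpncam` implements the workaround
used in weakly-supervised medical-image analysis: keep the pyramid features
frozen, replace the detection subnetworks with a global-average-pooling (GAP)
plus fully-connected (FC) softmax head over a chosen set of pyramid levels,
train only that head, and read saliency directly off its last convolutional
block. The motivating application is binary treatability screening of cervix
images ("treatable" vs "not treatable" for thermal ablation), where the
clinically meaningful evidence concentrates at a known landmark — the os and
the surrounding transformation zone — so a saliency map can be checked
against anatomy.

## The head

A pyramid backbone emits levels `P3..P7` at strides `8..128`, each with a
common channel width (256 for a full-scale backbone). A head is defined by an
ordered subset of levels. Every selected level is upsampled
(nearest-neighbour) to the grid of the finest selected level and the maps are
stacked along channels, giving a block with `K = channels x N_levels`
channels on an `H_f x W_f` grid. The head computes

    s_c = sum_k w_kc * F_k + b_c,      F_k = mean_{x,y} f_k(x, y)

followed by a two-class softmax. `F_k` is implemented as the spatial *mean*;
a sum convention would only rescale `w`, and the mean keeps the completeness
identity below free of grid-size factors. With two classes, the seven level
sets of interest are the five singletons, `{P3, P6, P7}` and `{P3..P7}`.

Nearest-neighbour upsampling is used for concatenation because it preserves
channel means exactly for integer scale factors; this both keeps the
relevance-map closed form exact and allows per-level pooled features to be
cached once and shared across head variants (`precompute_features()`).

## Saliency

Two maps are computed from the same block:

* **CAM** (class activation map), per class:
  `M_c(x, y) = sum_k w_kc f_k(x, y)`. No bias enters, values may be
  negative, and `mean_{x,y} M_c = s_c - b_c` (checked to `1e-5` in the
  tests).
* **CRM** (class-selective relevance map), class-agnostic: zero the whole
  `K`-vector at one location `L`, rerun the forward pass, and score
  `M(x, y) = sum_c (s_c - s_c(x, y))^2` over *all* output classes, so both
  supporting and opposing evidence register. Because the head is a pure
  GAP+FC map, zeroing location `(x, y)` shifts logit `c` by exactly
  `-M_c(x, y) / (H_f W_f)`, giving the closed form
  `M(x, y) = sum_c (M_c(x, y) / (H_f W_f))^2`. The package ships both the
  literal one-forward-pass-per-location oracle (`crm_bruteforce()`) and the
  closed form (`crm_closed_form()`); their agreement to `1e-5` relative is a
  standing test. Logits, not softmax probabilities, are used as the scores:
  the score definition is pre-softmax, and squared probability differences
  would saturate for confident heads.

Heatmap post-processing mirrors the usual practice: threshold at 20 % of the
map maximum ("maximum classification score" is read as the maximum *map*
value — thresholding a spatial map by a scalar class probability is
dimensionally incoherent), zero everything below it and all non-positive
values, min-max rescale survivors to `[1, 255]` (a degenerate constant
surviving set renders as 255), then bilinearly upsample to the input size and
rescale so the rendered maximum is exactly 255. Thresholding happens at
feature resolution *before* upsampling so that the RoI fraction — surviving
cells over total cells — is a statistic of the feature grid; a 15 %
threshold variant is available for maps judged too conservative, and the
15 % RoI provably contains the 20 % RoI. CAM's negative values are simply
dropped by the positive threshold, never rectified beforehand.

Localization is scored with a pointing game: a hit if the rendered map's
peak (first maximum in column-major order) falls within the ground-truth
landmark mask dilated by 4 px.

## Training protocol

Head training follows a frozen-feature protocol: images are resized so the
longer border is 1200 px (aspect preserved) and rescaled into `(0, 1)`; the
backbone is never updated (the test backbone is a pure closure, so this is
structural, and a probe-image invariance test enforces it); the FC layer is
randomly initialized (`sd 1e-3`) and trained with learning rate `1e-6` on
the cross-entropy, batch size 1; the returned head is the one from the epoch
with the lowest held-out validation loss, with the validation split taken at
the woman level (default 20 % of training women).

Two numerical choices deserve emphasis because they were forced by
measurement:

* **Optimizer.** With plain SGD at learning rate `1e-6`, the pooled
  features' scale anisotropy (channel standard deviations span two orders of
  magnitude across levels) leaves the head in the small-logit regime even
  after tens of millions of sample steps; the measured test accuracy
  plateaued far below the linear-separability ceiling of the same features
  (which a converged logistic fit attains). Adam at the *same* learning rate
  converges to that ceiling in a few million steps, which is why
  `head_config(optimizer = "adam")` is the default; plain SGD remains
  available and is used in the zero-learning-rate no-op tests. The SGD/Adam
  loop is compiled (Rcpp) with its own deterministic shuffle stream, so
  training is bit-reproducible for a fixed seed.
* **Feature conditioning.** Features are centred and scaled per channel by
  their training standard deviation floored at 10 % of the RMS channel
  scale, and the transform is folded back into `(w, b)` afterwards, so the
  delivered head is an exact affine map of the raw pooled features.
  Centering only shifts the bias; the scale floor matters because saliency
  reads the folded weights — an unfloored standardization amplifies
  near-constant channels by factors of `1e5` and visibly corrupts both CAM
  and CRM (this was observed, not hypothesized).
* **Epoch budget.** The default of 20000 epochs (batch-1 passes over a few
  hundred images) is what the `1e-6` learning rate requires to reach the
  validation-loss minimum; best-epoch selection makes the generous budget
  harmless. Selection uses validation loss rather than accuracy because
  accuracy saturates early on a separable problem and would freeze an
  under-trained head.

Class 1 ("not treatable") is the positive class for F1; ties at probability
0.5 predict positive, the clinically conservative choice.

## The synthetic study

Real cervigram data is not redistributable, so the package ships a generator
(`generate_sample()`, `generate_dataset()`) whose images contain exactly the
structure the pipeline is meant to exploit: a soft-edged elliptical organ
with low-frequency shading, a dark concave disc (the os-like landmark, the
ground-truth mask), and a class-dependent structure hugging that disc — a
thin smooth faint rim for class 0, and for class 1 a broad irregular bright
annulus carrying evidence at three spatial scales (smooth annular lift,
azimuthal lobes of roughly 20 px wavelength, and a strong few-px
interference texture). Datasets default to the 729:304 class ratio scaled
down, assign roughly 10 % of "women" two images, and split train/test at the
woman level (about 80/20).

The generator's constants were fixed once, at design time, to satisfy three
study conditions and were not revisited afterwards:

* a linear probe on mean landmark-region intensity separates the classes at
  99 % or better — the separability budget the trained head must meet but
  cannot exceed trivially, since the probe uses the ground-truth location
  while the head must find it;
* the discriminative evidence spans pyramid strides, so concatenated
  multi-level heads hold a genuine advantage over single levels (the ranking
  test asserts the direction, not any published number);
* the three evidence scales are stripped progressively by Gaussian blur:
  a `(19,19)` filter (auto sigma `0.3((k-1)/2 - 1) + 0.8`, about 3.2 px)
  removes the texture, a `(49,49)` filter (about 7.7 px) also removes the
  lobes and dilutes the annular lift, so the frozen head's accuracy falls
  strictly along the ladder instead of collapsing immediately to the
  majority floor. For the same reason the class-neutral scene content (os
  dip, ellipse edge, class-0 rim) is kept smooth at the few-pixel scale and
  global speckle is minimal: early versions with sharper neutral content
  shifted *all* logits so violently under blur that both blur levels
  collapsed to the majority class, hiding the ladder the experiment is
  about.

What passing tests on this generator do **not** show: robustness to the
nuisance structure of real photographs (specular highlights, instruments,
off-center framing, exposure variation), to label noise, or to backbones
whose features were learned rather than random. The synthetic study
validates the *mechanics* — training, saliency identities, localization
scoring, degradation bookkeeping — not clinical performance.

The bundled test backbone is a seeded seven-layer strided convolutional
stack (He-initialized, ReLU, reflective padding) emitting all five levels at
a configurable width. Reflective rather than zero padding is deliberate:
zero padding produces a constant activation ridge along feature-map borders
that dominates squared-magnitude saliency and pins CRM peaks to image edges.
The pipeline default width is 32 channels per level; at 16 channels the
linear ceiling of the pooled features dips below the 95 % study condition on
some seeds. The contract width for real backbones remains 256.

## Problem sizes and determinism

The shipped experiments use 256-px images: three replicates of a
500-image study (400 train / 100 test) for accuracy, localization and RoI
statistics, and ten replicates of a 207-image study for the blur ladder —
sizes chosen so a full run completes on a single CPU core in well under half
an hour. All randomness flows from explicit integer seeds through a single
fan-out helper; backbone weights, dataset composition, SGD shuffling and
initialization are each on their own stream, and every API that consumes
randomness restores the caller's RNG state.

## Known limitations

* The closed-form CRM is exact only for a pure GAP+FC head; any intermediate
  nonlinearity would require the brute-force path.
* The cached pooled-feature fast path refuses non-integer grid ratios
  (non-square or non-power-of-two-friendly sizes fall back to explicit block
  construction).
* The pretrained-backbone adapter is a contract (`extract_pyramid()`
  validates any callable honoring the level/stride/channel geometry), not a
  bundled network; all shipped experiments run on the seeded test backbone.
* `compare_roi()` implements the per-image mean of the relative RoI
  reduction; with very sharp maps the per-image ratio is noisy, and the
  aggregate mean RoI fractions are reported alongside it.
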
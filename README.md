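# fpncam

Feature-pyramid classification heads with CAM and CRM saliency, plus the
evaluation harness around them: heatmap rendering, region-of-interest (RoI)
quantification, pointing-game localization, and a Gaussian-blur degradation
ladder. The package targets the weakly-supervised workflow used in medical
image screening — here, deciding whether a cervix image is "treatable" by
thermal ablation — where a detector-style pyramid backbone is repurposed as
a whole-image classifier so its decisions can be visualized and checked
against anatomy (the os and transformation zone).

## What it implements

Given any backbone emitting pyramid levels `P3..P7` (strides 8–128, one
shared channel width), `fpncam` builds classification heads by selecting
levels, upsampling them (nearest-neighbour) to the finest selected grid and
concatenating along channels, then applying global average pooling and a
fully connected two-class softmax:

    s_c = Σ_k w_kc · mean_{x,y} f_k(x,y) + b_c

Only `(w, b)` are trained; the backbone stays frozen. Over the resulting
last convolutional block it computes two saliency maps:

- **CAM** — `M_c(x,y) = Σ_k w_kc f_k(x,y)`, the class-weighted activation
  sum, whose spatial mean equals `s_c − b_c`;
- **CRM** — `M(x,y) = Σ_c (s_c − s_c(x,y))²`, the squared change of *all*
  class logits when the feature vector at one location is zeroed. A literal
  zero-out brute force ships alongside an exact GAP+FC closed form,
  `M(x,y) = Σ_c (CAM_c(x,y)/(H_f W_f))²`, and the two are held to 1e-5
  agreement in the tests.

Heatmaps are thresholded at 20 % (or 15 %) of the map maximum, rescaled to
(0, 255] and upsampled to image size; RoI fractions, the CRM-vs-CAM RoI
comparison, and a pointing game against ground-truth landmark masks
quantify them. A degradation harness re-runs the frozen head on images
blurred with (1,1), (19,19) and (49,49) Gaussian filters and reports the
accuracy/saliency decay.

Because the original cervigram data is private, the package includes a
deterministic synthetic generator: two-class images with an os-like dark
disc and a class-dependent lesion whose evidence spans fine, medium and
coarse spatial scales, plus ground-truth masks, a 729:304-style class
imbalance, and a woman-level train/test split. A seeded convolutional test
backbone makes the whole pipeline runnable end to end with no downloads.

## Worked example

```r
library(fpncam)

man <- generate_dataset(c(353, 147), seed = 1)      # ~400 train / 100 test
bb  <- make_test_backbone(42, channels = 32)
head <- train_head(head_config(c("P3", "P6", "P7"), seed = 1),
                   manifest_split(man, "train"), bb)
evaluate_head(head, manifest_split(man, "test"), bb)
#> <evaluation_report> n = 99, accuracy = 1.0000, F1 = 1.0000
#>     predicted
#> true  0  1
#>    0 70  0
#>    1  0 29

s   <- get_sample(manifest_split(man, "test"), 1)
blk <- build_concatenated_block(extract_pyramid(s$image, bb), head$levels)
hm  <- render_heatmap(crm_closed_form(head, blk), dim(s$image)[1:2])
roi_fraction(hm)                      # share of feature cells kept at 20 %
pointing_game(hm, s$landmark_mask)    # TRUE: the peak sits on the landmark
write_heatmap_png(hm, "crm.png", image = s$image)  # warm overlay
```

The evaluation report counts the 70 treatable / 29 not-treatable test
images; F1 is computed for the minority positive ("not treatable") class.
`roi_fraction` is the fraction of feature-grid cells surviving the 20 %
threshold, and the pointing game checks that the heatmap peak falls within
4 px of the os-like landmark.

A thin CLI wraps the same functions
(`inst/cli/fpncam <synth|train|heatmap|compare-heads|degrade-eval> [...]`).

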
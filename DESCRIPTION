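Package: fpncam
Title: Feature-Pyramid Classification Heads with CAM and CRM Saliency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds image classifiers on top of frozen feature-pyramid
    (FPN-style) backbones by selecting, upsampling and concatenating pyramid
    levels P3-P7 into a last convolutional block followed by global average
    pooling and a linear two-class softmax head. Provides two saliency methods
    over that block: the class activation map (CAM) and the class-selective
    relevance map (CRM), the latter defined by the squared change in all class
    logits when the feature vector at one spatial location is zeroed, together
    with a literal zero-out brute-force oracle. Includes heatmap thresholding
    and rendering, region-of-interest quantification, a pointing-game
    localization metric, a Gaussian-blur degradation harness, a deterministic
    seeded test backbone, and a synthetic two-class image generator with
    ground-truth landmark masks so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
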
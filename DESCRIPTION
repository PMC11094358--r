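Package: earcount
Title: Density-Map-Augmented Instance Segmentation for Counting Wheat Ears
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Counts and segments wheat ears in field images with a
    YOLACT-style prototype/coefficient instance-segmentation network whose
    backbone attention uses generalized-mean (GeM) pooled CBAM gates and
    whose feature pyramid carries an auxiliary Gaussian density-map
    regression branch.  Provides labelme/COCO annotation conversion, image
    tiling and dataset splitting, Gaussian density-map targets and the
    density MSE loss, the composite training objective, greedy-NMS
    prediction with density-modulated scores, counting metrics
    (RMSE/Bias/R-squared) and mask-based COCO-style AP/mAP evaluation, and a
    seeded synthetic field-scene generator so the whole pipeline is testable
    end-to-end on CPU.  The network layers and reverse-mode gradients are
    implemented in pure R over base arrays with im2col convolutions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
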
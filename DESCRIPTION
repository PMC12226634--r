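Package: VideoReprompt
Title: Overseer-Guided Re-Prompting for Temporally Consistent Semantic
    Video Segmentation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for temporally consistent semantic segmentation of
    videos in which objects enter and leave the scene, modelled on
    surgical recordings. A frame-wise detection "overseer" monitors the
    class constellation of every frame and re-prompts a memory-based
    mask-propagation tracker when the constellation changes persistently,
    back-tracking to the first frame of the change and re-segmenting the
    intervening frames. The package ships a synthetic moving-shape scene
    generator with exact ground-truth optical flow, reference overseer
    and tracker implementations satisfying the same contracts as real
    detector/tracker backends, the detection multi-task loss (class
    cross-entropy, smooth-L1 box regression, per-pixel mask
    cross-entropy), optical-flow-warped temporal-consistency metrics
    (warped Dice/IoU, contour distance, inter-frame IoU) and per-frame
    detection metrics (class F1, bounding-box IoU and mask Dice at 50%
    IoU, semantic Dice), plus a command-line driver for reproducible
    generate/run/eval experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Software, Segmentation, Classification, Visualization
RoxygenNote: 7.3.3
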
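Package: odadetect
Title: Occlusion- and Density-Aware Detection Blocks for Small-Fruit Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Building blocks for detecting small, occluded, densely clustered
    fruits (e.g. coffee cherries) in orchard imagery: condition-guided windowed
    self-attention with relative position bias, space-to-depth downsampling
    with cascaded spatial and channel attention, and dual-branch dynamic
    upsampling via bilinear grid sampling.  Includes generators for per-pixel
    occlusion and clustering-density condition maps, a colorimetric (HSV/RGB)
    ripeness classifier, a deterministic synthetic orchard-scene generator
    with YOLO-format annotations, and a small CPU-trainable detector assembly
    with mAP\@0.5 evaluation.  All neural blocks run on a lightweight
    reverse-mode automatic-differentiation tape implemented in base R, so the
    package has no deep-learning framework dependency.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    png,
    tiff,
    jsonlite,
    stats,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
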
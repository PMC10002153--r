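Package: i3m
Title: Automated Third-Molar Maturity Index Measurement from Two-Part
    Tooth Segmentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the third-molar maturity index I3M = (a + b)/c on
    256x256 mandibular third-molar radiograph crops from a two-part
    (apical/coronal) instance segmentation. Implements two topological
    post-segmentation measurement engines: a radii-partition approach (TDA)
    that finds the root-canal midlines as the lines equidistant to the two
    instances and locates each apex's wall extremities, and a skeleton-based
    variant (TDA-DL) that fits an inverted-U medial axis to the apical mask
    and pairs its endpoints with the lowest coronal points. Includes labelme
    polygon annotation I/O, CLAHE preprocessing, seeded rotation/flip
    augmentation, IoU segmentation evaluation with confusion-map overlays,
    an agreement-statistics battery (paired t, McNemar, Pearson), the
    0.08 minor/adult decision rule, and a synthetic tooth-phantom generator
    with analytic ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    png,
    pracma,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    mgcv,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
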
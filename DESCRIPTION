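Package: isletmorph
Title: Granule Morphometry and Composition Pipelines for Pancreatic Islet Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipelines for pancreatic islet microscopy. Generates
    synthetic scanning-transmission electron microscopy (STEM) islet images with
    complete granule ground truth, segments secretory granules of the alpha, beta
    and delta classes from grayscale micrographs via overlapping tiles, separates
    touching granules with a seeded watershed, and computes per-granule and
    per-islet morphometrics including the beta-granule core-to-halo ratio.
    Companion modules quantify islet cell composition from multiplexed
    immunohistochemistry marker calls, compute glucose-tolerance-test areas under
    the curve, and dispatch group comparisons through normality- and
    variance-gated parametric or nonparametric tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    car,
    grDevices,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    nnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
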
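Package: ccmorph
Title: Deformation-Based Shape Morphometry of the Mid-Sagittal Corpus Callosum
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for localized shape analysis of the two-dimensional
    mid-sagittal corpus callosum: boundary-curve extraction from labeled
    segmentations with genu/body/splenium sub-region labels, area and
    regional-thickness measures, closest-to-mean-area template selection,
    rigid plus large-deformation diffeomorphic (LDDMM) curve registration
    with a currents data term, pointwise Jacobian-determinant deformation
    markers, and covariate-adjusted permutation inference with
    max-statistic family-wise error control, gender-by-group interaction
    testing and Cohen's d effect sizes. Includes a synthetic cohort
    generator that produces labeled corpus-callosum-like mask slices with
    controlled, localized group effects for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    graphics,
    grDevices,
    jsonlite,
    parallel,
    RNifti,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
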
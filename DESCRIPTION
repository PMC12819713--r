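Package: shrubelf
Title: Landscape Drivers and Environmental Limiting Factors of Tall-Shrub Cover
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for landscape-scale analysis of deciduous tall-shrub
    (Alnus/Salix) fractional cover: terrain derivatives (slope, flow
    accumulation, topographic wetness index), semivariogram patch-structure
    analysis, multi-scale random-forest driver importance, niche
    differentiation in standardized environmental space, stomatal-slope (g1)
    estimation from gas-exchange data, and environmental-limiting-factor (ELF)
    modeling of potential cover via 99th-quantile B-spline envelope regression
    combined by a Liebig minimum rule. Includes a synthetic landscape
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    ranger,
    splines,
    stats,
    tiff,
    tools,
    utils
Suggests:
    boot,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
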
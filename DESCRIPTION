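Package: ringmech
Title: Tensile Mechanics, Morphometry and Statistics for Ring-Shaped
    Engineered Tissue Constructs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Processes raw load-extension traces from uniaxial
    pull-to-failure tests of fibroblast-derived tissue rings into
    stress-strain curves and the three standard endpoints (ultimate
    tensile strength, maximum tangent modulus by sliding-window
    regression, failure strain), with drag-baseline subtraction,
    tension-onset gauge-length detection and engineering/true stress
    conversions.  Also quantifies ring thickness uniformity from
    annulus images (radial thickness profile, coefficient of
    variation), collagen content from dye-binding standard curves, and
    runs the group-comparison battery used in dose-response
    experiments (Shapiro-Wilk/Levene gate, one-way ANOVA with Tukey
    HSD, Kruskal-Wallis with Conover-Iman post-hoc, compact letter
    displays, Spearman/Bonferroni correlation matrices).  A synthetic
    data generator with known ground truth exercises the whole
    pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    png,
    withr,
    car,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
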
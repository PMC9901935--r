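Package: mcskin
Title: Quantification of Merkel Cell Innervation, Turnover, and Patterning in Zebrafish Skin
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image quantification and statistics for studying Merkel cells in
    the zebrafish epidermis. Provides synthetic confocal-stack and cohort
    generators with known ground truth, ImageJ-style measurement primitives
    (maximum projection, 8-bit conversion, Huang and Otsu thresholding,
    particle analysis, percent area), 3D nucleus detection, sphere-proximity
    innervation scoring with Wilson confidence intervals, photoconversion
    pulse-chase turnover accounting with half-life estimation, scale-aligned
    spatial distribution mapping, and a statistics layer covering ordinary and
    one-breakpoint segmented regression, the Johnson-Neyman technique, one-way
    ANOVA with Tukey HSD, and rank tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    yaml,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    withr
Config/testthat/edition: 3
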
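Package: psmmorph
Title: Morphometrics of Presomitic Mesoderm Morphogenesis in 3D Cell Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of presomitic mesoderm (PSM) morphogenesis
    from labelled 3D cell ensembles, as produced by tissue-grafting and
    optical-clearing experiments in axolotl embryos. Provides a synthetic
    tail-bud generator with configurable ground truth (per-region cell
    counts, ellipsoid shape and orientation distributions, cohesion and
    density scales, mitotic-spindle orientation, filopodia), moment-based
    ellipsoid fitting, orientation classification, per-section pairwise
    cohesion and closest-neighbour density statistics, tissue extent and
    volume measures, the relative-displacement metric d_rel along a body
    contour, and a reporting pipeline with one-way ANOVA group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    tiff,
    yaml
Config/testthat/edition: 3
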
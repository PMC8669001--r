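Package: nucquant
Title: Quantification of Nuclear Architecture, Gene-Locus Positioning and
    Focal Adhesions in Fluorescence Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures heterochromatin redistribution and mechanoresponse
    phenotypes from multi-channel fluorescence images: nuclear
    periphery/total and heterochromatic-foci/total mean-intensity ratios,
    size-normalized radial positions of DNA-FISH spots and their distance
    to the nearest heterochromatic focus, and per-cell focal-adhesion
    counts and areas after difference-of-Gaussian band-pass filtering.
    Includes a synthetic phantom generator with exact ground truth for
    validating every stage, and a nonparametric statistics layer
    (Mann-Whitney, Kruskal-Wallis with Dunn's post-hoc test) matching
    standard per-object reporting practice.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    yaml,
    jsonlite,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
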
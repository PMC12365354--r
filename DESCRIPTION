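Package: tonguespace
Title: Quantifying Midsagittal Lingual Articulation of Vowels from Tongue-Contour Landmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating scalar measures of tongue position, height and
    shape extracted from 11-knot midsagittal tongue-contour landmark data
    (ultrasound tongue imaging post-processed with landmark trackers).
    Computes a battery of 16 per-token measures (knot coordinates, highest
    point, highest vertex, triangle-based curvature ratios and the Modified
    Curvature Index), builds per-speaker non-metric multidimensional scaling
    reference vowel spaces, ranks all 64 position-by-height/shape measure
    pairs by Procrustes residual sum of squares, runs speaker-held-out linear
    discriminant vowel classification with a mixed-logistic error model, and
    performs within-speaker-scaled correlation analyses against vowel
    formants. A synthetic articulatory-cohort generator with known ground
    truth makes every stage testable without access to recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    vegan,
    lme4,
    jsonlite,
    tibble,
    dplyr
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
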
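Package: coralspat
Title: Spatial Pattern and Cluster Analysis of Coral Disease Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing the spatial structure of disease in
    transect-based coral surveys at two resolutions: transect level
    (presence/absence of disease in a transect) and colony level (each
    transect weighted by its counts of diseased and total colonies).
    Implements a weighted transformed Ripley's K (L-function) with
    simulation envelopes under complete spatial randomness, a
    disease-minus-population difference function with random-labeling
    envelopes, cross-resolution hypothesis tests, and DMAP-style
    spatially filtered prevalence surfaces with Monte Carlo hotspot
    detection, bandwidth selection via the optimised-bandwidth statistic
    and the standard distance. Includes a synthetic survey generator
    (uniform or Thomas-clustered transect placement, overdispersed
    colony counts, random/focal/ubiquitous disease scenarios) so every
    stage can be validated against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
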
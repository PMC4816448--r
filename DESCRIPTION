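Package: markerfill
Title: Reconstruction of Missing Marker Trajectories in Motion Capture Data
Version: 0.1.0
Authors@R: person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Fills gaps in optical motion-capture marker trajectories by
    exploiting the strong inter-correlations between markers in human
    movement data. A principal component basis is estimated from the
    gap-free time frames, a second basis from a copy with the corrupted
    marker columns zeroed, and missing coordinates are recovered through a
    transition between the two truncated score spaces. Markers near the
    gap are emphasised through automated Gaussian distance weighting. Two
    strategies handle gaps in multiple markers: simultaneous
    reconstruction (R1) and per-marker consecutive reconstruction with a
    distance-based inclusion rule (R2). The package also provides spline
    and linear interpolation baselines, readers and writers for CSV, TRC
    and C3D trajectory files, a synthetic gait generator, randomized
    gap-corruption protocols, and evaluation and sensitivity-analysis
    harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
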
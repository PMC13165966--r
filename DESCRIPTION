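Package: mdefov
Title: Extended Field-of-View Lensless Holography with Multi-Depth Phase Retrieval
Version: 0.1.0
Authors@R: person("MD-EFOV", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Tools for lensless in-line digital holography with an extended
    field of view (EFOV). Laterally scanned, defocused holograms are
    registered and stitched into an extended hologram at each of several
    sensor depths; a multi-depth amplitude-constrained iterative phase
    retrieval then recovers the complex wavefront at a reference plane,
    suppressing the twin image before object-plane reconstruction by the
    angular spectrum method. Includes a full synthetic forward model
    (USAF-style bar targets, blob phantoms, serpentine scan simulation)
    so every stage is testable without recorded data, plus resolution
    analysis utilities (fringe contrast, MTF10 criterion, system
    parameter formulas).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
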
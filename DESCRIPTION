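Package: dropletwin
Title: Digital Twin of a Self-Optimizing Capillary Droplet Reactor
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates a multi-step capillary droplet reactor for the
    synthesis of iron oxide/gold core-shell nanoparticles: droplet
    generation at a capillary junction, in-droplet injection of gold
    precursor at three downstream junctions, plug-flow transit, empirical
    gold-shell growth, and per-droplet optical transmission recorded as a
    noisy photodetector trace. Couples the twin to threshold-based droplet
    signal extraction and a one-dimensional step-contracting simplex
    optimizer, closing the loop so that autonomous discovery of optimal
    synthesis conditions can be reproduced, replicated and tested entirely
    in software. Includes particle size-distribution sampling and
    post-synthesis characterization utilities.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
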
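Package: ossomech
Title: Comparative Forelimb Muscle Moment-Arm Mechanics and Phylogenetic
    Morphospaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative musculoskeletal biomechanics of archosaur
    forelimbs. Builds articulated pectoral-girdle and forelimb models with
    three-axis joint coordinate systems, routes muscle strands around wrapping
    cylinders as shortest tangent-arc-tangent paths, and computes signed,
    size-normalized muscle moment arms by the tendon-excursion (muscle-tendon
    unit travel) method over standardized pose sweeps. Per-taxon summed
    moment-arm magnitudes feed phylogenetic principal components analysis under
    a Brownian-motion model on stratigraphically time-scaled trees, with
    uniform-branch-length and ordinary-PCA variants, osteometric correlation
    analyses, and posture and axis-placement sensitivity protocols. A
    synthetic-data module generates limb models with closed-form moment-arm
    oracles, Brownian trait tables on known trees, and study-shaped action
    tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    yaml,
    MASS,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    phytools,
    withr
Config/testthat/edition: 3
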
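Package: cxnav
Title: Central-Complex Circuit Models of Insect Multimodal Navigation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An agent-based simulator of the insect central-complex (CX)
    steering circuit and its coordination of multimodal guidance. Implements
    an eight-column heading-direction population code, the copy-and-shift
    mechanism that converts non-directional sensory change into desired
    headings, wind-projection-neuron (WPN) encoding of egocentric wind
    direction, a ring-attractor network for weighted integration of
    directional cues, and ON/OFF contextual switching between chemotaxis and
    odour-gated anemotaxis. Ships analytic odour landscapes (volcano, linear,
    Gaussian plume with constant wind), path-integration memory, working-memory
    manoeuvres (wind compensation and backtracking), experiment runners for
    fly chemotaxis/anemotaxis and ant homing with a conspecific-nest
    distractor, trajectory tibbles, summary metrics, and ggplot2 graphics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
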
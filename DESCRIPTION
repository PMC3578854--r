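Package: RNAPtraffic
Title: Sequence-Dependent Stochastic Simulation of Transcription
    Elongation with RNA Polymerase Collisions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Event-driven stochastic simulation of transcription elongation
    by one or many RNA polymerases on the same DNA template. Single-molecule
    kinetics follow a thermal-ratchet model in which the translocation
    equilibrium of the elongation complex is computed from nearest-neighbor
    nucleic-acid thermodynamics (DNA/DNA duplex and RNA/DNA hybrid), and
    nucleotide incorporation follows effective Michaelis-Menten kinetics;
    backtracking and recovery are modeled as thermally activated hops on the
    same free-energy landscape. A multi-polymerase event loop interpolates
    positions linearly between reactions, solves pairwise collision times,
    and resolves collisions by force transmission, pushing, or elastic
    exchange, enforcing hard-core exclusion. The analysis layer calls pause
    sites from dwell-time quantiles, measures backtracking distances,
    simulates transcription gels, computes relative transcription
    efficiency, and scores pause predictions against experimental pause
    lists with a clustered quality metric.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
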
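Package: symbiotax
Title: Realism-Based Representation of Symbiotic Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A toolkit for representing symbiotic interactions between
    individual organisms at the instance level. Provides a 34-class taxonomy
    of symbiosis subtypes (ecto/endo, mutualism through parasitoidism,
    obligatory and facultative refinements) with machine-readable differentia
    and a rule-based classifier of interaction profiles; a referent-tracking
    tuple store for particulars, temporal regions, instantiation and relation
    assertions; a consistency validator enforcing the axioms of the
    representation (minimum participants, interspecies requirement, spatial
    and temporal coherence, the neutralism contradiction); deterministic
    Turtle, OWL functional-syntax style and JSON exporters with lossless
    round-trip import; three worked host-symbiont scenario fixtures; and a
    seeded synthetic scenario generator with fault injection for
    negative testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
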
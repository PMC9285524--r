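Package: rvdesign
Title: Reaction-Vector Driven Pseudo-Retrosynthetic De Novo Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reaction-based de novo design engine. A query ligand is broken
    into key fragments with BRICS retrosynthetic rules, each fragment is used
    to retrieve similar purchasable building blocks from a catalogue by Morgan
    fingerprint similarity, and the building blocks are recombined with
    reaction vectors (signed atom-pair descriptor differences extracted from
    known reactions) into scored candidate molecules, each annotated with a
    virtual synthetic route. Includes corpus curation, an RV database format,
    a deterministic structure generator with exact descriptor-conservation
    verification, similarity-driven active and passive scoring, a command-line
    interface, and a synthetic fixture generator so the whole pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    yaml,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
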
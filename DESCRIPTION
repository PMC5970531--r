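Package: symbionet
Title: Reverse Ecology of Bacteriocyte Symbiont Communities by Metabolic
    Network Expansion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates per-genome metabolic capability in a defined
    bacteriocyte-like environment using the network-expansion (scope)
    algorithm, detects complementary (synergistic) metabolites for genome
    combinations, scores pairwise metabolic competition from
    topology-derived seed sets (effective metabolic overlap), and
    quantifies each genome's dependency on individual environment
    components via single-metabolite removal scans.  Includes generators
    for synthetic reaction universes with planted pathway structure, so
    that every pipeline stage can be validated against known ground
    truth, and packaged fixtures describing the whitefly (Bemisia tabaci)
    symbiont community.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
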
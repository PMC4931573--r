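Package: multipus
Title: Microbial Consortium Design by Directed Steiner Hypertrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Proposes minimum-cost microbial consortium designs from
    genome-scale metabolic networks. Metabolic networks of candidate worker
    organisms (and optional reference organisms) are assembled into a weighted
    directed hypergraph whose vertices are (compound, organism) pairs and whose
    hyperarcs are endogenous reactions, heterologous insertions and
    cross-organism metabolite transports. The Directed Steiner Hypertree
    problem - the minimum-weight hyperarc set rooted at the source compounds
    that produces all target compounds - is solved exactly by a
    fixed-parameter-tractable dynamic program over ordered combinations of
    multi-substrate (tentacular) hyperarcs, with complete enumeration of
    co-optimal designs. Includes a lossless pre-solve compression, a
    brute-force reference solver, a seeded random-instance generator, toy case
    studies, and TSV/SBML/JSON/DOT input-output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils-internal.R'
    'hypergraph-ops.R'
    'weights.R'
    'instance-builder.R'
    'compress.R'
    'steiner.R'
    'dsh-solver.R'
    'oracle.R'
    'generator.R'
    'fixtures.R'
    'io-network.R'
    'io-sbml.R'
    'io-instance.R'
    'io-solutions.R'
    'show-methods.R'
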
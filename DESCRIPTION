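Package: mhbi
Title: Semantic Annotation of Monogenean Haptoral Bar Images
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates the Monogenean Haptoral Bar Image (MHBI)
    ontology: a controlled vocabulary of seven concepts and twenty-seven
    properties (largely reusing TDWG LSID terms) for annotating digitised
    images of monogenean haptoral bars with their taxonomy and publication
    provenance. Provides a minimal RDF triple-graph model with Turtle and
    RDF/XML round-trip serialization, deterministic instance-naming rules,
    conversion of tabular specimen/taxon/publication records into instance
    triples, materialization of transitive, symmetric and inverse property
    entailments, an eight-test clarity plus twelve-test coherence structural
    validation battery, and merging of the parasite ontology with a host
    (Fish) ontology by promoting the isHostedIn property from literal- to
    object-valued. Includes a worked Bifurcohaptor baungi example dataset,
    a parametric synthetic-dataset generator, targeted schema mutants for
    every validator test, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    xml2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
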
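Package: hco
Title: Ontology-Based Representation and Querying of Tractography Connectomes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for ontology-based annotation and multi-granularity
    querying of in vivo human connectomics data. Builds the Human
    Connectomics Ontology (HCO) schema on top of a gross-anatomy view
    extracted from a frame-style neuroanatomy ontology, translates the view
    into description-logic class axioms with existential restrictions,
    converts thresholded tractography connectivity matrices into semantic
    annotations (MR_Node/MR_Route individuals), materializes entailments
    with a rule-based saturation engine (role hierarchy, inverses, symmetry,
    transitivity, one role chain, realization of defined classes), and
    answers Manchester-style class-expression queries, including the four
    medial-BA6 competency queries. Ships a deterministic mini neuroanatomy
    fixture and a synthetic five-subject cohort generator with planted
    SMA-like and pre-SMA-like connectivity so the full pipeline runs
    offline, plus cross-subject term-overlap statistics.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
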
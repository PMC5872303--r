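Package: luxrbgc
Title: Mining and Characterization of LuxR-Linked Biosynthetic Gene Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies biosynthetic gene clusters (BGCs) physically linked to
    LuxR-family quorum-sensing regulators from annotated cluster records and
    HMMER domain-hit tables, removes clusters whose only biosynthetic gene is a
    luxI-type signal synthase, dereplicates hits by greedy protein-identity
    clustering at a configurable cutoff, and characterizes the retained
    clusters by luxI co-occurrence, cluster type, habitat, taxonomic class,
    GC-content anomaly, diagnostic-residue LuxR subtype, and neighbor-joining
    phylogeny with p-distance, complete gap deletion, bootstrap support, and
    outgroup rooting. Includes a synthetic-data generator that emulates
    antiSMASH-style cluster records with planted LuxR/LuxI genes and a
    controlled family structure of sequence identities, so every stage of the
    pipeline is testable against ground truth without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    jsonlite,
    methods,
    phytools,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
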
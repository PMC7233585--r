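Package: locfrust
Title: Local Frustration Profiling and Clustering of Polymorphic Protein Receptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes decoy-normalized local frustration indices on
    residue-level coarse-grained structure models of receptor-ligand
    complexes, evolutionary importance scores (per-column information
    content and real-value Evolutionary Trace ranks) from multiple
    sequence alignments, per-allele frustration profiles including
    ligand-removal deltas, and single-linkage clustering of alleles by
    frustration profile. Ships a synthetic-data generator producing toy
    complexes, alignments and profile matrices with known ground truth,
    and an end-to-end deterministic pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    ape,
    jsonlite,
    seqinr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
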
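Package: genopotential
Title: Genome-Resolved Metabolic Potential Profiling for Metagenome Bins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Interprets metagenome-assembled genomes from anoxic subsurface
    communities: scans proteomes for the CXXCH heme-binding motif to call
    multiheme cytochromes and predict dissimilatory iron reducers, types
    hydrogenases by cofactor and resolves electron-bifurcating [FeFe] Group A3
    enzymes from monomeric Group A1 forms by operon context, profiles
    biogeochemical pathway completeness from marker-gene rules, computes bin
    completeness and contamination from single-copy marker sets, dereplicates
    near-identical bins by pairwise nucleotide identity, ranks organisms by
    ribosomal protein S3 marker abundance, and prepares concatenated
    ribosomal-protein alignments for phylogenetics. Ships a deterministic
    synthetic-community generator with planted ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
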
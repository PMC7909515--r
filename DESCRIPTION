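Package: gvscan
Title: Detection of Giant Virus (NCLDV) Signatures in Assembled Sequence Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores assembled contigs, metagenome-assembled genomes and
    eukaryotic scaffolds for signatures of nucleo-cytoplasmic large DNA
    viruses (NCLDVs, "giant viruses"). Each predicted ORF receives a reward
    from its best match against a library of giant virus orthologous group
    (GVOG) profiles and a penalty from its best Pfam match, both normalized
    by how often the family occurs in NCLDV versus Caudovirales genomes, and
    the two are combined on a square-root scale. Per-ORF scores are
    summarized as contig means or rolling-window tracks, contigs are
    classified as NCLDV or non-NCLDV at a score cutoff, maximal
    positive-scoring runs of ORFs are reported as putative endogenous viral
    regions, and hits to ten conserved NCLDV marker genes are tabulated.
    Also includes benchmarking utilities (pseudocontig shredding,
    sensitivity and specificity at the cutoff, N50-based dereplication of
    genome clusters, genome quality filters) and a synthetic-fixture
    generator so the whole pipeline runs without external binaries or
    reference databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
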
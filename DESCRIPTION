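Package: ppaphylo
Title: Progressive Phylogenetic Analysis, Clock Dating and mtDNA
    Introgression Discordance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for progressive phylogenetic analysis (PPA) of
    mitochondrial sequence samplings: simulation of clock-evolved
    alignments on dated species and locus trees with lineage-capture
    introgression events, pairwise distance estimation (p, JC69, K2P),
    neighbor-joining and UPGMA inference, Fitch parsimony with exhaustive
    topology search at toy scale, ordered taxon addition with
    attachment-edge recording and monophyly/paraphyly classification,
    single-calibration molecular-clock node dating, and topology
    discordance analysis that detects displaced taxa and infers the
    direction of an mtDNA introgression from sister-group structure.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape (>= 5.0),
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
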
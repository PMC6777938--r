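Package: corecruit
Title: Evolution of Co-Repressor Recruitment Motifs in Notch Pathway Proteins
Version: 0.1.0
Authors@R:
    person("corecruit", "maintainers", email = "corecruit@example.org",
           role = c("aut", "cre"))
Description: Comparative-genomics toolkit for studying how transcription
    factors recruit the Groucho and CtBP co-repressors, built around the
    Su(H)/Hairless/S-CAP/MTA gene families of protostomes. Provides
    degenerate short-linear-motif scanning and PSSM scoring with
    threshold calibration, mapping of protein motifs onto gene models to
    test splice-junction and phase conservation across genes, gene-family
    microsynteny detection and orientation classification, Fitch and
    Dollo parsimony reconstruction of binary character gain and loss on a
    species tree, verification of printed expression-construct and primer
    sequences, and a seeded synthetic-data generator that emits FASTA,
    GFF3, newick and character-matrix inputs with ground truth for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
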
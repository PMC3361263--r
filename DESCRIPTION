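Package: ancestryAIC
Title: Model-Selection Tests of Common Ancestry for Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Fits independent-origins and common-origin phylogenetic
    hypotheses for two gene families by maximum likelihood under standard
    nucleotide (JC, K80, HKY, GTR, +Gamma) and amino-acid (Poisson, JTT,
    mtmam, +F, +Gamma) substitution models and compares them with the
    Akaike information criterion. Includes a Clustal-style progressive
    aligner with explicit affine gap-open/gap-extension penalties so the
    sensitivity of the test to alignment can be swept, and a
    sequence-evolution simulator with mitochondrial-style codon-position
    composition bias so the behaviour of the test on truly unrelated
    families can be studied without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ape,
    phangorn,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
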
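Package: paretarget
Title: Degradome-Guided MicroRNA Target Validation and Expression
    Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for degradome (PARE) guided analysis of plant
    microRNA-mRNA regulation: position-weighted complementarity scoring
    of miRNA:target duplexes, exact-match mapping of degradome 5' tags
    onto a transcriptome, classification of candidate cleavage sites
    into the five t-plot abundance categories, exact-test differential
    expression calls for small-RNA and transcript count matrices, and
    the integration step that joins differentially expressed miRNAs,
    validated cleavage sites and differentially expressed targets into
    reversed-regulation pair tables. Includes a fully seeded synthetic
    experiment generator (transcriptome, planted target sites, degradome
    tags, negative-binomial count matrices) with recoverable ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
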
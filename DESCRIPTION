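Package: captaxa
Title: Organism Term Recognition and Normalization in Figure Captions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Recognizes organism and species mentions in the figure captions of
    biomedical articles and links them to NCBI Taxonomy identifiers. Implements
    a multistage pipeline: a character-trie lexicon matcher with bounded
    edit-distance search, full-text meta-information gathering (pre-linked ID
    counts, abbreviation pairs), majority-rule and convolutional neural network
    disambiguation, context-dependent resolution of common terms such as
    "embryo" and "larva", and the strict/overlap span-level plus caption-level
    normalization micro-PRF evaluation protocol used by the BioCreative Bio-ID
    track. Reads and writes BioC XML collections and ships a deterministic
    synthetic corpus generator so the whole pipeline is testable without any
    corpus download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
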
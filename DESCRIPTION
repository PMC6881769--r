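Package: kmersig
Title: Alignment-Free Genome Comparison with Normalized K-mer Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores every possible k-mer in a genome or sequence-region set on
    a normalized -1..+1 over/under-representation scale against a zero-order
    Markov background, compares species by Pearson correlation of their k-mer
    signatures, selects biologically relevant k-mers (mean + 2 SD rule,
    repetitive-k-mer and abundance filters, genus-common k-mers), matches
    candidate k-mers against JASPAR-style position frequency matrices, and
    clusters species into UPGMA, WPGMA and neighbor-joining trees from 1 - CC
    distances. Includes a deterministic synthetic-genome simulator with
    controlled composition, planted k-mers, tandem repeats and clade
    structure for validation without any genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    phangorn,
    stats,
    utils,
    grDevices,
    graphics,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
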
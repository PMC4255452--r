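Package: pia
Title: Phylogenetically-Informed Annotation of Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Annotates candidate members of curated gene families in
    transcriptome assemblies by maximum-likelihood placement onto
    pre-calculated reference gene trees carrying functionally
    characterized landmark genes. Provides six-frame ORF extraction,
    local-alignment homolog search with Karlin-Altschul E-values,
    profile alignment of queries onto fixed reference alignments, a WAG
    amino-acid substitution model with Felsenstein pruning likelihoods,
    an evolutionary placement algorithm with jplace output, landmark
    based annotation reports, reference-package construction and
    validation, and a sequence simulator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
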
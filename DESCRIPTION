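Package: pgannotate
Title: Proteogenomic Functional Annotation of Predicted Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotation engine for predicted proteomes. Consumes tabular
    similarity-search results against a curated and a user-specified protein
    database, domain and family scan outputs, transcript quantification and
    peptide-spectrum matches, and decides for each protein whether it can be
    annotated by similarity transfer, is a hypothetical protein, or has no
    database support. Annotations are validated with transcript (TPM) and
    peptide (q-value) evidence, every protein is placed in one of eight
    evidence categories, and the results are written as annotated FASTA,
    rewritten GFF3, TXT and TSV files together with summary statistics. A
    fixture generator produces complete synthetic input sets with planted
    ground truth so the whole engine is testable without external tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
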
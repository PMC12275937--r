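Package: sepsieve
Title: Discovery and Quantitative Analysis of Small ORF-Encoded Peptides
    from Shotgun Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies small ORF-encoded peptides (SEPs, microproteins) from
    peptide-spectrum matches by a four-criterion novelty filter (no identity
    to the annotated reference proteome, minimum peptide length, a minimum
    run of consecutive b/y fragment ions, and minimum b/y ion coverage of the
    spectrum), annotates identified SEPs (start-codon class, transcript
    class, ProtParam instability index, MS sequence coverage), and carries
    the label-free quantitative downstream: total-abundance normalization,
    low-abundance missing-value imputation, paired tumor/normal fold change,
    differential calling, fuzzy c-means clustering of grade trends and
    per-SEP ROC AUC. Ships a synthetic-data generator that emulates every
    input so the whole pipeline is testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    e1071,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
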
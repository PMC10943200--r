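Package: goprose
Title: Summarizing Gene Ontology Annotations into UniProt-Style Function Paragraphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for turning a protein's set of Gene Ontology (GO) term
    annotations into a concatenated description document and summarizing it
    into UniProt-style Function, Subunit structure and Pathway paragraphs with
    a trainable encoder-decoder. Includes GO-overlap redundancy clustering for
    dataset construction, seeded 80/10/10 splits, beam-search generation with a
    beam-probability confidence score, embedding-based and optimal-transport
    mover similarity evaluation metrics, protein-centric Fmax evaluation of
    predicted GO terms, GO deletion/addition robustness protocols, and a fully
    synthetic fixture generator so the whole pipeline runs without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
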
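Package: ntermatlas
Title: Functional Mapping of Amino Acid Usage at Protein N-Termini
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects functional biases in amino acid usage at the N-terminus of
    proteins, with a focus on position 2 (the residue after the initiator
    methionine, which determines methionine aminopeptidase cleavage and
    N-terminal acetyltransferase targeting). Implements signed log-space
    hypergeometric bias scores (HGT scores) that remain finite for p-values
    far below double precision, positional aspecificity scores, a Gene
    Ontology term scan with greedy BestN/BestF redundancy reduction,
    mitochondrial targeting sequence (MTS) signature profiling within and
    across species, threshold-independent analysis of selective
    translating-ribosome affinity purification (sel-TRAP) enrichment data,
    and seeded synthetic-data generators for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
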
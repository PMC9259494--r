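Package: coevomap
Title: Interface Inference for Protein Complexes from Genome-Proximity
    Paired Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers and validates protein-protein interfaces in multi-chain
    complexes from inter-protein co-evolution. Builds paired multiple sequence
    alignments by concatenating homologue pairs that are co-located on the
    same nucleotide record (an operon proxy), applies coverage, gene-separation,
    sequence-identity and gap-ratio filters, scores co-evolving inter-protein
    residue pairs either by aggregating distance-bin probability tensors
    (distograms) at a contact cutoff or with a built-in mutual-information
    scorer with average-product correction, selects top-ranked pairs by
    threshold or rank rules, and maps them onto multi-chain atomic structures
    to measure minimal cross-chain C-alpha distances and interface precision.
    Includes a fully seeded synthetic-data generator (genomes, coupled
    alignments, toy symmetric structures) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
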
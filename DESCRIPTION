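Package: syntenica
Title: Synteny Blocks, Contig Scaffolding and Genome Rearrangement Analysis
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Comparative-genomics toolkit for ordering draft supercontigs into
    chromosomes and quantifying genome rearrangement between related species.
    Infers one-to-one orthologues from reciprocal hit tables, chains anchors
    into signed locally collinear blocks, scaffolds contigs against reference
    genomes under subtelomeric and pericentromeric marker constraints, computes
    exact double-cut-and-join (DCJ) rearrangement distances with typed sorting
    scenarios and multichromosomal-distance summaries, extracts and annotates
    rearrangement breakpoints, and tests the random breakage model against the
    exponential segment-length law with a parametric bootstrap. Ships a
    simulator of multichromosomal genomes with known rearrangement histories
    that grounds every analysis step in recoverable truth.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    Biostrings,
    rtracklayer,
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
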
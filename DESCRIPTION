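Package: tegc
Title: GC Content of Transposable Elements and Genome Composition in Fish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the nucleotide composition of fish genomes
    and their transposable elements (TEs). Computes GC content of arbitrary
    sequence sets, partitions soft-masked genome assemblies into repetitive
    (GC_REP) and non-repetitive (GC_NONREP) fractions, classifies isochore
    bands, parses TE consensus libraries in the RepeatMasker
    'name#Class/Superfamily' dialect and pools consensus GC by TE class and
    group, assembles cross-species trait tables and runs the associated
    correlation analyses (genome size vs. TE density, genome size vs. genomic
    GC with salmonid exclusion, consensus TE GC vs. genomic GC, repetitive
    vs. non-repetitive GC). A deterministic synthetic-data generator plants
    compositional structure in simulated species panels so the whole pipeline
    can be exercised and validated without any external downloads.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
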
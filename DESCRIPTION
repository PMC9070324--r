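Package: mycosieve
Title: Extracting and Profiling Fungal Communities Hidden in Plant Transcriptome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to separate microbial (fungal) transcripts from host-plant de novo
    transcriptome assemblies and to characterize the resulting communities. Implements
    representative-isoform selection with expression and ORF-length gates, assembly summary
    statistics (N50), host-versus-fungus separation by top-hit taxonomic voting, phylum-level
    consensus classification with a TPR/FPR benchmarking harness, SPM tissue-specificity
    calling, hypergeometric term enrichment against a custom background, transporter and
    secreted-CAZyme threshold filters, and fully seeded synthetic-data generators with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
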
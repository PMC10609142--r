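Package: cpgmeta
Title: Curation and Descriptive Analytics of Complete Prokaryotic Genome Metadata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline curation and exploration of complete prokaryotic genome
    (CPG) metadata. Reads the tab-delimited NCBI genome-reports dialect,
    counts chromosomes and plasmids by parsing the replicon field, resolves
    seven-rank taxonomic lineages (superkingdom to species) from NCBI
    taxdump flat files, filters genomes by taxonomy and genomic features,
    and computes the descriptive statistics behind common comparative
    questions: five-number summaries, Pearson correlations among genomic
    features, submissions per year, per-rank distribution tables,
    prevalence percentages, and the 2x2 chi-square test of independence.
    Includes a seeded synthetic fixture generator that emits a matched
    genome report, mini taxdump, and ground-truth manifest so the whole
    pipeline is testable without network access, plus a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
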
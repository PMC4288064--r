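Package: snprisk
Title: Personal SNP-Based Disease Risk Assessment from Direct-to-Consumer Genotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and queries a curated knowledge base of SNP-disease
    associations with evidence and impact grading, parses direct-to-consumer
    raw genotype files (23andMe-style TSV), and assesses personal prostate
    cancer risk through independent-association scores, cumulative models
    with reference-table odds-ratio lookup, probabilistic branch-set models
    with three-valued verdicts, and polygenic scoring (count, log-odds, and
    multiplicative lifetime-risk methods). Includes a seeded synthetic-genome
    generator for end-to-end validation against planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
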
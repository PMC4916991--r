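Package: promlit
Title: Compound Promiscuity and Bioactivity Records in Light of
    Publication Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for curating ChEMBL-style compound bioactivity tables
    into high-confidence data sets, aggregating potency measurements into
    unique compound-target activity records with their source
    publications, profiling the publications behind them, and quantifying
    compound promiscuity (the number of distinct protein targets a
    compound is reported active against) cross-tabulated against
    publication frequency.  A synthetic corpus generator with a
    ground-truth manifest supports end-to-end validation of every
    pipeline stage without access to the source database.
License: MIT + file LICENSE
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
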
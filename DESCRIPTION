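Package: cwrgap
Title: Ex Situ Gap Analysis and Climate-Change Prioritisation for Crop Wild Relatives
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing how well a crop gene pool is represented in
    genebank collections and for prioritising wild relatives for collecting
    under climate change. Parses MCPD-style passport data, computes
    per-taxon and per-country representation statistics against a gene-pool
    registry with native-range information, grids and spatially thins
    occurrence records, fits a small ensemble niche model (climate envelope
    plus logistic regression) evaluated with the true skill statistic and
    AUC, projects suitability to future climate scenarios, derives range
    change under full-migration and no-migration assumptions, and assigns
    rule-based collecting priorities that combine Red List status,
    collection counts and projected range loss. Ships the published
    rapeseed (Brassica napus) gene-pool inventory, range-change and
    priority tables as worked fixtures, and a synthetic-data generator so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
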
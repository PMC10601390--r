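Package: ethnophylo
Title: Phylogenetic Patterns in Ethnobotanical Use Guilds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Community-phylogenetic analysis of binary use traits (guilds)
    on a dated phylogeny, as applied in ethnobotany: grafting study species
    onto a dated megatree at genus or family crown nodes and pruning to the
    study list; the Fritz-Purvis D statistic for binary traits with
    random-shuffle and Brownian-threshold permutation nulls; Faith's PD,
    MPD and MNTD with standardized effect sizes against a tip-pool null;
    PhyloSor phylogenetic beta diversity decomposed into true turnover and
    nestedness components with tip-shuffle SES scores; and a permutation
    "hot node" scan for clades enriched in a focal use. Includes a
    synthetic-data generator (Yule trees, clade-respecting taxonomies,
    guild tables with known clustering structure) so every stage is
    testable without external data, and a pipeline driver that produces
    the full set of result tables from a single configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape (>= 5.0),
    phytools,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    picante,
    withr
Config/testthat/edition: 3
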
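Package: beebias
Title: Auditing Research-Effort Bias Across Bee Taxa
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to audit how research effort maps onto bee taxa. Builds
    deduplicated document sets from bibliographic exports and counts genus
    mentions with a Porter-stemmed inverted index over an alias library;
    computes genus-level centrality (species strength, Bluethgen's d') from
    bipartite plant-pollinator interaction matrices with within-network
    z-scoring and region-balanced aggregation; quantifies trait-space
    coverage and overlap with kernel-density isopleths and permutation
    nulls after residualising traits on genus principal components; and
    fits the bias statistics (popularity expectations, quadrant policy
    groups, richness-effort scaling with HC3 errors and influence trims,
    Welch/Games-Howell family comparisons, binomial share trends, and
    negative-binomial count models with exposure offsets). Includes seeded
    synthetic-data generators with known ground truth so the whole pipeline
    is testable end to end without licensed corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    withr,
    optparse
Config/testthat/edition: 3
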
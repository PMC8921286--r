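Package: ckinet
Title: Network Pharmacology Screening for Compound Kushen Injection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the network-pharmacology screening
    pipeline used to nominate anti-colorectal-cancer mechanisms of Compound
    Kushen Injection (CKI), a two-herb preparation (Kushen + Baituling).
    Provides drug-likeness compound screening, per-compound target selection by
    normalized fit score, multi-source disease-gene aggregation, evidence
    intersection, herb-compound-target tripartite network construction with
    descriptive graph statistics, protein-protein interaction hub detection by
    the degree-above-mean rule, hypergeometric overrepresentation analysis with
    Benjamini-Hochberg correction (EASE variant optional), three-way pathway
    consensus, and the 0-12 immunoreactive score used for immunohistochemistry.
    A seeded synthetic-fixture generator emulates the database extracts the
    screen consumes, with planted overlaps and spiked pathways recorded in a
    ground-truth manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
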
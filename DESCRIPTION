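Package: abforge
Title: Building Non-Redundant Collections of Paired Antibody Variable Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assembling a single non-redundant collection of paired
    antibody (immunoglobulin) light and heavy chain variable-region sequences
    from heterogeneous protein FASTA sources. Chains are classified from header
    metadata, grouped by entry identifier, paired by a four-strategy cascade
    (header containment, two-member groups, sequence evidence from previously
    paired antibodies, and curated decisions), standardized to variable regions
    bounded by known start and end motifs, and merged across sources with
    containment deduplication, longest-common-substring resolution of terminal
    sequence divergence, isolation of ambiguous chain-sharing clusters, and
    cross-species duplicate removal. Records carry provenance-preserving merged
    headers, stable SHA-256 content identifiers, and optional best-hit germline
    V-segment assignments. A seeded fixture generator with machine-readable
    ground truth supports end-to-end testing without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    digest,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    openssl,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
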
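Package: phytabkit
Title: Phytab Multi-Gene Data Format, Supermatrix Concatenation and Gene-Tree Utilities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for multi-gene (multi-partition) phylogenetic data kept in
    the four-column tab-delimited 'phytab' format (species, partition, unique
    id, sequence). Provides format conversion (FASTA, TNT xread, relaxed
    phylip, Nexus), record-level pruning and deduplication, per-partition
    alignment quality control (gap-column masking, similar-sequence removal,
    length outliers), coverage-filtered supermatrix concatenation with RAxML
    partition files and occupancy reports, native neighbor-joining trees from
    p-distances, NJst-style species-tree estimation from gene trees by
    average internode distance, bipartition bootstrap support, long-branch
    diagnostics, patristic distances, taxon pruning and tree thinning, plus
    deterministic synthetic-data simulators and a subcommand-style command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
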
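---
title: "Methods and design notes for phytabkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for phytabkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytabkit)
```

This vignette records how the methods in `phytabkit` are defined, the
choices made where a convention had to be fixed, and what the bundled
simulators do and do not emulate. The README shows the user-facing
workflow; here we document semantics.

## The phytab format

A phytab file is tab-delimited with exactly four columns and no header:
species, partition (gene family), unique id, sequence. Record order is
significant and preserved by every read/write cycle. Conventions we fixed:

* **No header row.** Tabular tools downstream expect pure data lines;
  blank lines are skipped on read.
* **Extra columns are tolerated** (with a warning) so that annotated
  phytab files — e.g. with an appended per-gene evolutionary-rate column —
  still parse; only the first four fields are used.
* **Empty uid** is written as a `"."` sentinel so the column count never
  drops below four, and read back as the empty string.
* **Character validation is permissive**: sequences may be nucleotide,
  amino acid, or morphological symbols, with `-` as gap and `?` as
  missing, because the same container carries molecular and morphological
  partitions. Only emptiness and embedded tabs/newlines are rejected.

## Coverage filtering

`filter_coverage()` applies, in order: an optional species-list
restriction; a one-shot aligned-length minimum (lengths never change, so
this needs no iteration); then two occupancy rules iterated to a fixed
point — drop partitions with fewer than `min_species_per_gene` species,
drop species with fewer than `min_genes_per_species` partitions. The rules
alternate, and each application that removes something counts as one
logged "round", so a species stranded at zero genes by a gene removal
appears in the round after that removal. Iteration is necessary: a single
pass can leave survivors that violate the thresholds they were checked
against before the other rule fired. The fixed-point definition makes the
operation idempotent, which the test suite checks by exhaustive recount on
randomized fixtures.

## Supermatrix construction

* **Ordering.** Partitions and species appear in order of first appearance
  in the input. Any deterministic order would do; first-appearance is
  stable under record-preserving transformations and reproducible.
* **Missing character.** Default `?`, which both RAxML and morphological
  matrices accept; `-` is selectable where a downstream tool insists on
  it.
* **Models.** A two-column gene/model table (the output format of
  per-gene model-selection runs) assigns models; partitions without an
  entry default to GTR when ≥ 90% of their non-gap symbols are
  `A/C/G/T/U`, otherwise WAG. The cutoff only routes the *default*; an
  explicit table always wins.
* **Duplicates.** More than one record per (species, partition) is an
  error rather than a silent overwrite, and the message points at
  `find_duplicates()`, whose default key is exactly this pair.
* **The "phylipE" dialect** is defined here as relaxed sequential phylip:
  a `ntax nchar` header, then one `name␣sequence` line per species with
  the name untruncated and a single space separator. Strict phylip
  truncates/pads to 10 characters and refuses post-truncation collisions.
* **Coordinates** in partition files are 1-based inclusive
  (`GTR, g01 = 1-148`), the RAxML convention; nothing 0-based is ever
  exposed.

## Distances and neighbor joining

The p-distance between two rows is mismatches over compared positions,
where compared positions are jointly non-gap (`-`, `?`) sites within the
overlap; unaligned pairs are compared over the shorter length. A pair with
no comparable site is an error, not a silent zero. The Jukes–Cantor
correction −¾ ln(1 − 4p/3) diverges as p → ¾, so p ≥ 0.75 raises an error
suggesting the uncorrected distance.

`nj_tree()` is the standard Q-criterion agglomeration. Two numerical
choices make it deterministic and safe:

* **Tie-breaking.** Exact ties on the minimum of Q are resolved by the
  lexicographically lowest active-index pair. Ties are common in small
  symmetric fixtures (e.g. additive quartets), and an unspecified order
  would make outputs run-to-run unstable.
* **Clamping.** Negative intermediate branch lengths — expected on
  non-additive input — are clamped to zero with a single warning, the
  common practice in distance-method implementations.

Branch lengths are serialized at 15 significant digits, so path sums on
additive matrices reproduce the input within 1e-9, which the tests assert;
topologies on 4–5 taxa are additionally checked against a brute-force
least-squares fit over every unrooted topology, and against `ape::nj()` on
noisy matrices.

## NJst-style species trees

The internode distance between two leaves of one gene tree is the number
of internal nodes on the path between them — equivalently path edges minus
one — computed after suppressing degree-2 nodes and ignoring branch
lengths; rooting is irrelevant. If a species appears as several leaves of
one gene tree, the distance is averaged over leaf pairs. Per species pair
the distances are averaged over the gene trees containing both species,
and neighbor joining on the averaged matrix gives the species tree. Two
consequences users should know:

* A species pair that never co-occurs in any gene tree leaves the matrix
  undefined; this is an error listing the pairs (typically a sign that
  coverage filtering was skipped), not an imputation.
* Branch lengths of the species tree are averaged internode counts —
  useful for topology, meaningless as time or substitutions.

## Bipartition support

Support for each internal edge of the unrooted reference is 100 × the
fraction of input trees whose unrooted bipartition set contains the same
split, rounded to the nearest integer and written as the internal node
label — the most portable Newick convention. Input trees must carry
exactly the reference's leaf set; trees with missing taxa are rejected
(listing the symmetric difference) rather than renormalized, because
partial-overlap support has no single accepted definition. Support is
invariant to input order and to rooting of the inputs, which the tests
check explicitly.

## QC filters

* **Column masking** removes columns whose gap fraction (`-` and `?`
  counted as gaps) strictly exceeds the threshold, so 1.0 is the identity
  and 0.0 removes every gapped column; removal is monotone in the
  threshold and idempotent.
* **Similar-sequence removal** is greedy first-wins representative
  selection within each partition: scanning in input order, a record is
  dropped when its identity to any already-kept record of that partition
  reaches the threshold. This is deterministic, order-stable, and
  guarantees every kept pair sits below the threshold; it is *not* a
  globally optimal clustering, and a different input order can keep a
  different (equally valid) representative set. Per-partition scope
  matches the per-gene parallelism of the phytab design.
* **Length outliers** are sequences whose ungapped length is strictly
  below `fraction ×` the mean ungapped length of their group (partition,
  or whole file for FASTA input). The default `fraction = 1` means simply
  "shorter than average"; 0.5 is a practical setting for flagging
  fragments.

## Synthetic data

`simulate_phytab()` emulates the one property that drives the
concatenation machinery: patchy, independent gene-by-species presence at a
set occupancy, with per-gene lengths and point substitutions from a shared
ancestral sequence. Defaults (20 species × 10 genes at 60% occupancy,
lengths 100–400, 5% per-site mutation) describe a small but realistically
sparse multi-gene project. It does **not** simulate realistic sequence
evolution — no tree-structured descent, no rate variation, no indels — so
gene trees estimated *from simulated sequences* are near-star topologies.
Tests that need topological signal therefore use
`simulate_gene_trees()`, which perturbs a model tree with one random NNI
with probability `swap_rate` per tree and resamples branch lengths from a
lognormal (meanlog log 0.1, sdlog 0.5 — the scale and spread typical of
per-gene branch lengths). NNI was chosen as the perturbation because it
yields an expected model-topology agreement of exactly `1 − swap_rate`,
which binomial bounds can check. Passing tests on these fixtures show the
machinery is correct under its stated model; they do not certify
performance on real alignments with alignment error, paralogy, or deep
coalescent conflict.

Both generators take one explicit integer seed, save and restore the
caller's RNG state, and are byte-reproducible for identical arguments.

## Problem sizes and runtime

The test-suite fixtures are deliberately small and numerous: 100
randomized datasets for round trips, 50 for filter fixed points, 4–9-taxon
trees for the brute-force oracles (the exhaustive topology scan grows as
the double factorial and is only feasible there), and 200 gene trees for
the NJst recovery check. The full suite runs in well under a minute on one
core; the NJ implementation is O(n³) in taxa and comfortable into the low
hundreds of taxa, beyond which a dedicated large-scale NJ tool is the
right choice.

## Known limitations

* NJ and NJst are the only native tree estimators; likelihood and Bayesian
  estimation are out of scope by design — the package prepares their
  inputs (supermatrix, partition file, per-gene alignments) instead.
* The TNT reader accepts only the minimal `xread` dialect (no polymorphic
  states, no command blocks); Nexus support covers trees blocks and simple
  sequential DATA blocks.
* Leaf-stability and branch-attachment-frequency statistics are not
  implemented; no agreed formula was available to implement faithfully.
* `remove_similar()` compares all pairs within a partition (O(k²)
  identities); for very deep per-gene sampling a dedicated clustering tool
  is more appropriate.
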
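# Native tree computation: Newick/Nexus I/O, p-distances, neighbor joining,
# gene-tree tables, NJst species trees, bipartition support, long-branch
# diagnostics, patristic distances, pruning and thinning.
#
# Trees are ape "phylo" objects throughout; collections are "multiPhylo".
# Trees are treated as unrooted wherever bipartitions or internode counts
# are involved; rooted Newick is accepted and interpreted.

#' Parse trees from Newick or Nexus text
#'
#' Newick input holds one tree per line (a trailing semicolon each);
#' \code{nexus-trees} reads a Nexus TREES block. Unbalanced parentheses and
#' duplicate leaf labels are rejected with informative errors.
#'
#' @param text tree text (string or lines) or a file path.
#' @param format \code{"newick"} or \code{"nexus-trees"}.
#' @return a \code{multiPhylo} list of trees.
#' @export
parse_trees <- function(text, format = c("newick", "nexus-trees")) {
  format <- match.arg(format)
  is_path <- length(text) == 1L && !grepl("[\n();]", text) && file.exists(text)
  if (format == "newick") {
    lines <- if (is_path) readLines(text, warn = FALSE)
             else if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]]
             else text
    lines <- trimws(lines)
    lines <- lines[lines != ""]
    trees <- lapply(seq_along(lines), function(i) {
      ln <- lines[i]
      depth <- cumsum(ifelse(strsplit(ln, "")[[1]] == "(", 1L,
                             ifelse(strsplit(ln, "")[[1]] == ")", -1L, 0L)))
      if (any(depth < 0) || utils::tail(depth, 1) != 0)
        stop("newick parse error on tree ", i, ": unbalanced parentheses ",
             "(first imbalance near position ",
             if (any(depth < 0)) which(depth < 0)[1] else nchar(ln), ")")
      tr <- ape::read.tree(text = ln)
      if (is.null(tr)) stop("newick parse error on tree ", i)
      tr
    })
  } else {
    path <- if (is_path) text else {
      tf <- tempfile(fileext = ".nex")
      writeLines(if (length(text) == 1L) strsplit(text, "\n")[[1]] else text, tf)
      tf
    }
    got <- ape::read.nexus(path)
    trees <- if (inherits(got, "phylo")) list(got) else unclass(got)
  }
  for (i in seq_along(trees)) {
    dup <- unique(trees[[i]]$tip.label[duplicated(trees[[i]]$tip.label)])
    if (length(dup))
      stop("duplicate leaf label(s) in tree ", i, ": ",
           paste(dup, collapse = ", "))
  }
  structure(trees, class = "multiPhylo")
}

#' Write trees as Newick or Nexus
#'
#' @param trees a \code{phylo} or list/\code{multiPhylo} of trees.
#' @param format \code{"newick"} (one tree per line) or \code{"nexus-trees"}.
#' @param path optional output file.
#' @return the serialized text (invisibly when written).
#' @export
write_trees <- function(trees, format = c("newick", "nexus-trees"),
                        path = NULL) {
  format <- match.arg(format)
  if (inherits(trees, "phylo")) trees <- structure(list(trees),
                                                   class = "multiPhylo")
  if (!inherits(trees, "multiPhylo"))
    trees <- structure(trees, class = "multiPhylo")
  if (format == "newick") {
    txt <- paste0(paste(vapply(trees, ape::write.tree, character(1)),
                        collapse = "\n"), "\n")
    if (is.null(path)) return(txt)
    cat(txt, file = path)
    return(invisible(txt))
  }
  tf <- if (is.null(path)) tempfile(fileext = ".nex") else path
  ape::write.nexus(trees, file = tf, translate = TRUE)
  txt <- paste0(paste(readLines(tf, warn = FALSE), collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  invisible(txt)
}

# ---- distances -------------------------------------------------------------

#' Validate a distance matrix
#'
#' @param m square numeric matrix with matching row/column labels.
#' @param tol symmetry tolerance.
#' @return the matrix (labels synchronized), or an error.
#' @export
validate_distance_matrix <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || !is.numeric(m) || nrow(m) != ncol(m))
    stop("distance matrix must be a square numeric matrix")
  if (is.null(rownames(m)))
    stop("distance matrix needs row/column labels")
  if (is.null(colnames(m))) colnames(m) <- rownames(m)
  if (!identical(rownames(m), colnames(m)))
    stop("distance matrix row and column labels differ")
  if (max(abs(m - t(m))) > tol) stop("distance matrix is not symmetric")
  if (max(abs(diag(m))) > tol) stop("distance matrix diagonal is not zero")
  if (min(m) < -tol) stop("distance matrix has negative entries")
  m
}

#' Pairwise p-distance (optionally Jukes-Cantor corrected) matrix
#'
#' The uncorrected distance between two rows is mismatches divided by
#' compared positions, counted over jointly non-gap sites
#' (\code{-}/\code{?} excluded). The \code{jc} correction applies
#' \eqn{-\frac{3}{4}\ln(1 - \frac{4}{3}p)} for nucleotide data; it is
#' undefined at \eqn{p \ge 0.75} and such pairs raise an error suggesting
#' \code{correction = "none"}.
#'
#' @param a an alignment (see [as_alignment()]), at least two rows.
#' @param correction \code{"none"} or \code{"jc"}.
#' @return a labeled symmetric distance matrix.
#' @export
p_distance_matrix <- function(a, correction = c("none", "jc")) {
  correction <- match.arg(correction)
  a <- as_alignment(a)
  if (length(a) < 2) stop("need at least two sequences")
  m <- aln_matrix(a)
  ok <- !(m %in% GAP_CHARS)
  dim(ok) <- dim(m)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(names(a), names(a)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    comp <- ok[i, ] & ok[j, ]
    if (!any(comp))
      stop("no jointly non-gap positions for pair ",
           names(a)[i], " / ", names(a)[j])
    p <- sum(m[i, comp] != m[j, comp]) / sum(comp)
    if (correction == "jc") {
      if (p >= 0.75)
        stop("Jukes-Cantor undefined for pair ", names(a)[i], " / ",
             names(a)[j], " (p = ", signif(p, 4),
             " >= 0.75); use correction = \"none\"")
      p <- -0.75 * log(1 - 4 * p / 3)
    }
    D[i, j] <- D[j, i] <- p
  }
  D
}

# ---- neighbor joining ------------------------------------------------------

#' Neighbor-joining tree from a distance matrix
#'
#' Standard agglomeration on the Q-criterion
#' \eqn{Q_{ij} = (n-2) d_{ij} - r_i - r_j}: the pair minimizing Q is joined,
#' branch lengths to the new node follow the usual rate-corrected split, and
#' distances to the remaining nodes are reduced. Exact ties on Q are broken
#' by the lexicographically lowest label-index pair, making the output
#' deterministic. Negative intermediate branch lengths are clamped to zero
#' with a warning. The result is returned unrooted (trifurcating root).
#'
#' @param m a labeled distance matrix with at least three taxa.
#' @return an unrooted \code{phylo} tree with branch lengths.
#' @examples
#' m <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' nj_tree(m)
#' @export
nj_tree <- function(m) {
  D <- validate_distance_matrix(m)
  if (nrow(D) < 3) stop("neighbor joining needs at least 3 taxa")
  frag <- rownames(D)            # newick fragment per active node
  clamped <- FALSE
  bl <- function(x) {
    if (x < 0) { clamped <<- TRUE; x <- 0 }
    sprintf("%.15g", x)
  }
  while (nrow(D) > 3) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    hit <- which(Q == min(Q), arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]
    dij <- D[i, j]
    bi <- 0.5 * dij + (r[i] - r[j]) / (2 * (n - 2))
    bj <- dij - bi
    newfrag <- paste0("(", frag[i], ":", bl(bi), ",", frag[j], ":", bl(bj), ")")
    others <- setdiff(seq_len(n), c(i, j))
    dnew <- 0.5 * (D[i, others] + D[j, others] - dij)
    D <- D[others, others, drop = FALSE]
    D <- rbind(cbind(D, dnew), c(dnew, 0))
    frag <- c(frag[others], newfrag)
    rownames(D) <- colnames(D) <- paste0("n", seq_len(nrow(D)))
  }
  d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
  b1 <- (d12 + d13 - d23) / 2
  b2 <- (d12 + d23 - d13) / 2
  b3 <- (d13 + d23 - d12) / 2
  nwk <- paste0("(", frag[1], ":", bl(b1), ",", frag[2], ":", bl(b2), ",",
                frag[3], ":", bl(b3), ");")
  if (clamped)
    warning("negative branch length(s) clamped to 0")
  ape::read.tree(text = nwk)
}

# ---- gene-tree tables ------------------------------------------------------

#' Construct a gene-tree table
#'
#' The multi-gene analogue of phytab for trees: an ordered set of
#' (partition, tree) pairs with unique partition labels, serialized as
#' two-column tab-delimited text (partition, newick).
#'
#' @param trees named list of \code{phylo} trees (names = partitions), or
#'   unnamed list plus \code{partitions}.
#' @param partitions optional partition labels.
#' @return an object of class \code{"gene_tree_table"} (a named list of
#'   \code{phylo}).
#' @export
gene_tree_table <- function(trees, partitions = names(trees)) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  if (is.null(partitions) || any(partitions == ""))
    stop("every gene tree needs a partition label")
  if (anyDuplicated(partitions))
    stop("duplicate partition label(s): ",
         paste(unique(partitions[duplicated(partitions)]), collapse = ", "))
  stopifnot(length(partitions) == length(trees))
  structure(stats::setNames(trees, partitions), class = "gene_tree_table")
}

#' @export
print.gene_tree_table <- function(x, ...) {
  cat("gene-tree table:", length(x), "partition(s)\n")
  for (p in utils::head(names(x), 8))
    cat("  ", p, ": ", length(x[[p]]$tip.label), " leaves\n", sep = "")
  if (length(x) > 8) cat("  ...\n")
  invisible(x)
}

#' @rdname gene_tree_table
#' @param path two-column tab-delimited file (partition, newick).
#' @export
read_gene_tree_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 2L))
    stop("gene-tree table lines must be 'partition<TAB>newick'")
  trees <- lapply(f, function(v) parse_trees(v[2])[[1]])
  gene_tree_table(trees, vapply(f, `[`, character(1), 1))
}

#' @rdname gene_tree_table
#' @param g a gene-tree table to serialize.
#' @export
write_gene_tree_table <- function(g, path = NULL) {
  txt <- paste0(names(g), "\t",
                vapply(unclass(g), ape::write.tree, character(1)), "\n",
                collapse = "")
  if (is.null(path)) return(txt)
  cat(txt, file = path)
  invisible(txt)
}

#' Estimate one neighbor-joining tree per partition
#'
#' For each partition of an aligned phytab dataset: build the p-distance
#' matrix (optionally Jukes-Cantor corrected) over its species and run
#' [nj_tree()]. Partitions with fewer than three species are skipped with a
#' warning. Each partition is computed independently, so results do not
#' depend on partition processing order.
#'
#' @param d a phytab dataset, aligned within partitions.
#' @param correction passed to [p_distance_matrix()].
#' @return a [gene_tree_table()] keyed by partition.
#' @export
phytab_gene_trees <- function(d, correction = "none") {
  validate_phytab(d)
  parts <- unique(d$partition)
  trees <- list(); kept <- character()
  for (p in parts) {
    sub <- d[d$partition == p, , drop = FALSE]
    if (length(unique(sub$species)) < 3L) {
      warning("partition '", p, "' has fewer than 3 species; skipped")
      next
    }
    a <- stats::setNames(sub$sequence, sub$species)
    trees[[length(trees) + 1L]] <- nj_tree(p_distance_matrix(a, correction))
    kept <- c(kept, p)
  }
  gene_tree_table(trees, kept)
}

# ---- NJst species tree -----------------------------------------------------

#' Average internode distance matrix over gene trees
#'
#' The internode distance between two leaves of one tree is the number of
#' internal nodes on the path between them (equivalently, path edges minus
#' one) after suppressing degree-2 nodes; branch lengths are ignored. When a
#' species appears as several leaves of one gene tree the distance is
#' averaged over leaf pairs. Per species pair, distances are averaged over
#' the gene trees in which both occur.
#'
#' @param g a gene-tree table (or list of \code{phylo}).
#' @param species_of function mapping a leaf label to its species (default:
#'   identity, i.e. leaves are labeled by species).
#' @return labeled symmetric matrix of average internode distances over the
#'   species union; an error lists species pairs that never co-occur.
#' @export
internode_distance_matrix <- function(g, species_of = identity) {
  trees <- if (inherits(g, "gene_tree_table")) unclass(g) else g
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("need at least one gene tree")
  species <- sort(unique(unlist(lapply(trees, function(t)
    species_of(t$tip.label)))))
  if (length(species) < 2) stop("need at least two species across gene trees")
  k <- length(species)
  tot <- matrix(0, k, k, dimnames = list(species, species))
  cnt <- matrix(0L, k, k, dimnames = list(species, species))
  for (tr in trees) {
    tr <- ape::collapse.singles(ape::unroot(tr))
    tr$edge.length <- rep(1, nrow(tr$edge))
    ed <- stats::cophenetic(tr) - 1     # path edges - 1 = internal nodes
    sp <- species_of(rownames(ed))
    for (a in unique(sp)) for (b in unique(sp)) {
      if (a >= b) next
      block <- ed[sp == a, sp == b, drop = FALSE]
      tot[a, b] <- tot[a, b] + mean(block)
      cnt[a, b] <- cnt[a, b] + 1L
    }
  }
  miss <- which(upper.tri(cnt) & cnt == 0, arr.ind = TRUE)
  if (nrow(miss))
    stop("species pair(s) never co-occur in any gene tree: ",
         paste(apply(miss, 1, function(ij)
           paste(species[ij[1]], species[ij[2]], sep = "/")), collapse = ", "))
  avg <- tot / pmax(cnt, 1L)
  avg[lower.tri(avg)] <- t(avg)[lower.tri(avg)]
  diag(avg) <- 0
  avg
}

#' NJst-style species tree from gene trees
#'
#' Computes the average internode distance matrix across gene trees
#' ([internode_distance_matrix()]) and runs neighbor joining on it. Branch
#' lengths of the result are in units of averaged internode counts, not
#' substitutions or time.
#'
#' @inheritParams internode_distance_matrix
#' @return list with \code{tree} (unrooted \code{phylo}) and
#'   \code{distances} (the averaged matrix).
#' @export
njst_species_tree <- function(g, species_of = identity) {
  avg <- internode_distance_matrix(g, species_of)
  if (nrow(avg) < 3) stop("NJst needs at least three species")
  list(tree = nj_tree(avg), distances = avg)
}

# ---- bipartition support ---------------------------------------------------

# canonical keys for the non-trivial splits of an unrooted tree: each split
# is represented by its side containing the alphabetically first leaf
split_keys <- function(tr) {
  tr <- ape::collapse.singles(ape::unroot(tr))
  nt <- length(tr$tip.label)
  if (nt < 4 || is.null(tr$Nnode) || tr$Nnode < 2) return(character())
  desc <- tip_descendants(tr)
  all_tips <- sort(tr$tip.label)
  root <- nt + 1L
  keys <- character()
  for (node in (nt + 1L):(nt + tr$Nnode)) {
    if (node == root) next
    side <- desc[[node]]
    if (length(side) < 2L || length(side) > nt - 2L) next
    if (!(all_tips[1] %in% side)) side <- setdiff(all_tips, side)
    keys <- c(keys, paste(sort(side), collapse = "\r"))
  }
  unique(keys)
}

tip_descendants <- function(tr) {
  nt <- length(tr$tip.label)
  desc <- vector("list", nt + tr$Nnode)
  for (i in seq_len(nt)) desc[[i]] <- tr$tip.label[i]
  ed <- stats::reorder(tr, "postorder")$edge
  for (k in seq_len(nrow(ed)))
    desc[[ed[k, 1]]] <- c(desc[[ed[k, 1]]], desc[[ed[k, 2]]])
  desc
}

#' Map bipartition support from a tree set onto a reference tree
#'
#' For every internal edge of the unrooted reference, support is
#' \eqn{100 \times} the fraction of input trees containing the same
#' bipartition of the leaf set, rounded to the nearest integer and written
#' as the internal node label (the usual bootstrap-support convention).
#' All input trees must have exactly the reference's leaf set; support is
#' invariant to input-tree order and rooting.
#'
#' @param reference a \code{phylo} tree.
#' @param trees a list/\code{multiPhylo} of trees over the same leaves.
#' @return the unrooted reference with integer support node labels
#'   (root label empty).
#' @export
tree_support <- function(reference, trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  ref_set <- sort(reference$tip.label)
  for (i in seq_along(trees)) {
    ts <- sort(trees[[i]]$tip.label)
    if (!identical(ts, ref_set)) {
      dif <- c(setdiff(ref_set, ts), setdiff(ts, ref_set))
      stop("tree ", i, " leaf set differs from reference: ",
           paste(dif, collapse = ", "))
    }
  }
  counts <- table(unlist(lapply(trees, split_keys)))
  ref <- ape::collapse.singles(ape::unroot(reference))
  nt <- length(ref$tip.label)
  desc <- tip_descendants(ref)
  all_tips <- ref_set
  labels <- character(ref$Nnode)
  root <- nt + 1L
  for (node in (nt + 1L):(nt + ref$Nnode)) {
    if (node == root) next
    side <- desc[[node]]
    if (length(side) < 2L || length(side) > nt - 2L) next
    if (!(all_tips[1] %in% side)) side <- setdiff(all_tips, side)
    key <- paste(sort(side), collapse = "\r")
    n <- if (key %in% names(counts)) counts[[key]] else 0L
    labels[node - nt] <- as.character(round(100 * n / length(trees)))
  }
  ref$node.label <- labels
  ref
}

# ---- long-branch diagnostics -----------------------------------------------

#' Flag anomalously long terminal branches across gene trees
#'
#' A terminal (leaf-subtending) edge is flagged when its length exceeds
#' \code{threshold} (mode \code{"absolute"}) or \code{threshold} times the
#' mean terminal edge length of its own tree (mode \code{"factor-of-mean"},
#' the default with threshold 3). Long terminal branches often signal
#' contaminant sequences, paralogs, or alignment artifacts; the flagged
#' partition list can be fed to [prune_records()] to drop the offending
#' genes.
#'
#' @param g a gene-tree table (or named list of \code{phylo} with branch
#'   lengths on all terminal edges).
#' @param mode \code{"factor-of-mean"} or \code{"absolute"}.
#' @param threshold positive real.
#' @return list with \code{report} (data.frame: partition, leaf, length,
#'   tree_mean, rule) and \code{flagged_partitions} (partitions with at
#'   least one flag).
#' @export
long_branch_report <- function(g, mode = c("factor-of-mean", "absolute"),
                               threshold = 3) {
  mode <- match.arg(mode)
  stopifnot(threshold > 0)
  trees <- if (inherits(g, "gene_tree_table")) unclass(g) else g
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (is.null(names(trees)))
    names(trees) <- paste0("tree", seq_along(trees))
  rows <- list()
  for (p in names(trees)) {
    tr <- trees[[p]]
    nt <- length(tr$tip.label)
    term <- tr$edge[, 2] <= nt
    if (is.null(tr$edge.length) || anyNA(tr$edge.length[term]))
      stop("tree '", p, "' is missing terminal branch lengths")
    len <- tr$edge.length[term]
    leaf <- tr$tip.label[tr$edge[term, 2]]
    mu <- mean(len)
    cut <- if (mode == "absolute") threshold else threshold * mu
    rule <- if (mode == "absolute")
      sprintf("length > %g", threshold)
    else sprintf("length > %g x tree mean %.6g", threshold, mu)
    hit <- which(len > cut)
    if (length(hit))
      rows[[p]] <- data.frame(partition = p, leaf = leaf[hit],
                              length = len[hit], tree_mean = mu,
                              rule = rule, stringsAsFactors = FALSE)
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(partition = character(), leaf = character(),
               length = numeric(), tree_mean = numeric(),
               rule = character(), stringsAsFactors = FALSE)
  rownames(report) <- NULL
  list(report = report, flagged_partitions = unique(report$partition))
}

# ---- pruning, thinning, patristic distances --------------------------------

#' Prune taxa from one or more trees
#'
#' Removes the named leaves; resulting degree-2 nodes are suppressed with
#' their incident branch lengths summed, so patristic distances among the
#' surviving taxa are unchanged. Names absent from a tree are warned about
#' and ignored; pruning a tree below two leaves is an error.
#'
#' @param trees a \code{phylo} or list/\code{multiPhylo}.
#' @param taxa leaf labels to remove.
#' @return pruned tree(s), same shape of input (single tree in, single
#'   tree out).
#' @export
prune_taxa <- function(trees, taxa) {
  single <- inherits(trees, "phylo")
  if (single) trees <- list(trees)
  out <- lapply(seq_along(trees), function(i) {
    tr <- trees[[i]]
    missing <- setdiff(taxa, tr$tip.label)
    if (length(missing))
      warning("taxa not in tree ", i, ": ", paste(missing, collapse = ", "))
    hit <- intersect(taxa, tr$tip.label)
    if (length(tr$tip.label) - length(hit) < 2L)
      stop("pruning tree ", i, " would leave fewer than 2 leaves")
    if (!length(hit)) return(tr)
    ape::drop.tip(tr, hit)
  })
  if (single) out[[1]] else structure(out, class = "multiPhylo")
}

#' Thin a tree list
#'
#' Keeps trees at indices 1, 1+step, 1+2*step, ... -- the usual
#' burn-in-free sub-sampling of a posterior tree sample.
#'
#' @param trees list/\code{multiPhylo}.
#' @param step positive integer sampling interval.
#' @return thinned \code{multiPhylo}.
#' @export
thin_trees <- function(trees, step) {
  stopifnot(step >= 1, step == round(step))
  structure(unclass(trees)[seq(1, length(trees), by = step)],
            class = "multiPhylo")
}

#' Patristic distances for leaf pairs
#'
#' The patristic distance between two leaves is the sum of branch lengths
#' along the unique path connecting them.
#'
#' @param t a \code{phylo} with branch lengths.
#' @param pairs two-column matrix/data.frame of leaf label pairs, or
#'   \code{NULL} for all \eqn{n(n-1)/2} unordered pairs.
#' @return data.frame: a, b, distance.
#' @export
pd_pairs <- function(t, pairs = NULL) {
  if (is.null(t$edge.length)) stop("tree has no branch lengths")
  D <- stats::cophenetic(t)
  labs <- rownames(D)
  if (is.null(pairs)) {
    idx <- which(upper.tri(D), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    out <- data.frame(a = labs[idx[, 1]], b = labs[idx[, 2]],
                      distance = D[idx], stringsAsFactors = FALSE)
  } else {
    pairs <- as.matrix(pairs)
    unknown <- setdiff(unique(as.vector(pairs)), labs)
    if (length(unknown))
      stop("unknown leaf label(s): ", paste(unknown, collapse = ", "))
    out <- data.frame(a = pairs[, 1], b = pairs[, 2],
                      distance = D[cbind(pairs[, 1], pairs[, 2])],
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
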
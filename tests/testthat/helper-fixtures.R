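# Shared fixture builders and independent oracles used across the suite.

# random phytab dataset with awkward-but-valid labels, occasional empty uids
# and gap/missing characters in sequences
rand_phytab <- function(n = 20) {
  lab <- function(k) paste0(sample(c(letters, LETTERS, 0:9, "_", "."),
                                   k, replace = TRUE), collapse = "")
  species <- replicate(n, lab(sample(3:12, 1)))
  partition <- sample(paste0("gene", 1:5), n, replace = TRUE)
  uid <- ifelse(runif(n) < 0.2, "",
                replicate(n, lab(sample(4:10, 1))))
  seqs <- replicate(n, paste0(sample(c("A", "C", "G", "T", "-", "?"),
                                     sample(5:40, 1), replace = TRUE,
                                     prob = c(rep(0.22, 4), 0.06, 0.06)),
                              collapse = ""))
  phytab(species, partition, uid, seqs)
}

# aligned multi-gene phytab: every partition has uniform length
rand_aligned_phytab <- function(n_species = 8, n_genes = 4, occupancy = 0.7) {
  sim <- simulate_phytab(n_species = n_species, n_genes = n_genes,
                         occupancy = occupancy, length_range = c(10, 30),
                         mutation_rate = 0.1,
                         seed = sample.int(1e6, 1))
  sim
}

# additive distance matrix of a tree (independent of nj_tree's internals)
tree_distance_matrix <- function(tr) {
  D <- cophenetic(tr)
  D[sort(rownames(D)), sort(rownames(D))]
}

# pairs x edges indicator matrix: which edges lie on each tip-pair path
path_edge_matrix <- function(tr) {
  nt <- length(tr$tip.label)
  edge_key <- paste(pmin(tr$edge[, 1], tr$edge[, 2]),
                    pmax(tr$edge[, 1], tr$edge[, 2]))
  pairs <- t(utils::combn(nt, 2))
  X <- matrix(0, nrow(pairs), nrow(tr$edge))
  for (k in seq_len(nrow(pairs))) {
    path <- ape::nodepath(tr, pairs[k, 1], pairs[k, 2])
    for (s in seq_len(length(path) - 1)) {
      key <- paste(min(path[s], path[s + 1]), max(path[s], path[s + 1]))
      X[k, match(key, edge_key)] <- 1
    }
  }
  list(X = X, pairs = pairs)
}

# brute-force oracle: best topology for distance matrix D by unconstrained
# least-squares fit of branch lengths over every unrooted topology
best_topology_by_ls <- function(D) {
  labs <- rownames(D)
  topos <- phangorn::allTrees(length(labs), rooted = FALSE, tip.label = labs)
  rss <- vapply(topos, function(tp) {
    pe <- path_edge_matrix(tp)
    d <- D[cbind(tp$tip.label[pe$pairs[, 1]], tp$tip.label[pe$pairs[, 2]])]
    fit <- qr.solve(crossprod(pe$X), crossprod(pe$X, d))
    sum((pe$X %*% fit - d)^2)
  }, numeric(1))
  topos[[which.min(rss)]]
}

same_topology <- function(t1, t2) {
  phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)) == 0
}

# brute-force recount of the coverage-filter thresholds on a phytab dataset
coverage_counts <- function(d) {
  list(genes_per_species = tapply(d$partition, d$species,
                                  function(x) length(unique(x))),
       species_per_gene = tapply(d$species, d$partition,
                                 function(x) length(unique(x))))
}

quartet_tree <- function(nwk) ape::read.tree(text = nwk)
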
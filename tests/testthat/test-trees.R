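test_that("parse_trees/write_trees round trip newick and nexus", {
  tr <- parse_trees("((A:1,B:2):0.5,C:3);")[[1]]
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_equal(sort(tr$edge.length), c(0.5, 1, 2, 3))

  set.seed(61)
  for (rep in 1:20) {
    t0 <- ape::rtree(sample(4:12, 1))
    back <- parse_trees(write_trees(t0))[[1]]
    expect_true(same_topology(t0, back))
    expect_equal(sort(back$edge.length), sort(t0$edge.length),
                 tolerance = 1e-8)
  }
  trees <- structure(replicate(3, ape::rtree(5), simplify = FALSE),
                     class = "multiPhylo")
  nx <- write_trees(trees, "nexus-trees")
  back <- parse_trees(nx, "nexus-trees")
  expect_length(back, 3)
  for (i in 1:3) expect_true(same_topology(trees[[i]], back[[i]]))
  back2 <- parse_trees(write_trees(back))
  for (i in 1:3) expect_true(same_topology(trees[[i]], back2[[i]]))

  expect_error(parse_trees("((A,B),C;"), "unbalanced")
  expect_error(parse_trees("((A,B),(A,C));"), "duplicate leaf")
})

test_that("p-distance counts mismatches over jointly non-gap sites", {
  expect_true(all(p_distance_matrix(c(a = "ACGT", b = "ACGT",
                                      c = "ACGT")) == 0))
  D <- p_distance_matrix(c(x = "AAAA", y = "AATT"))
  expect_equal(D["x", "y"], 0.5)
  expect_equal(p_distance_matrix(c(x = "ACGT", y = "ACGT"),
                                 correction = "jc")["x", "y"], 0)
  # gap-aware overlap
  D2 <- p_distance_matrix(c(x = "A-GT", y = "ACGA"))
  expect_equal(D2["x", "y"], 1 / 3)
  expect_error(p_distance_matrix(c(x = "--AA", y = "TT--")), "non-gap")
  expect_error(p_distance_matrix(c(x = "AAAA", y = "TTTT"),
                                 correction = "jc"), "0.75")
  # jc agrees with the closed form (and with ape on DNA data)
  D3 <- p_distance_matrix(c(x = "AAAAAAAAAA", y = "AAAAAAAATT"),
                          correction = "jc")
  expect_equal(D3["x", "y"], -0.75 * log(1 - 4 * 0.2 / 3))
  bin <- ape::as.DNAbin(matrix(c(strsplit("aaaaaaaaaa", "")[[1]],
                                 strsplit("aaaaaaaatt", "")[[1]]),
                               2, 10, byrow = TRUE,
                               dimnames = list(c("x", "y"), NULL)))
  expect_equal(D3["x", "y"], as.matrix(ape::dist.dna(bin, "JC69"))["x", "y"],
               tolerance = 1e-12)
})

test_that("nj_tree solves the 3-taxon case in closed form", {
  m <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(m)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("A", "B", "C")], c(A = 1, B = 2, C = 3))
})

test_that("nj_tree recovers additive trees and their distances", {
  # the worked 4-taxon additive matrix from tree ((A:1,B:2):1,(C:3,D:4))
  labs <- c("A", "B", "C", "D")
  m <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4, dimnames = list(labs, labs))
  tr <- nj_tree(m)
  expect_true(same_topology(tr, quartet_tree("((A,B),(C,D));")))
  internal <- tr$edge.length[tr$edge[, 2] > length(tr$tip.label)]
  expect_equal(internal, 1)
  expect_equal(cophenetic(tr)[labs, labs], m, tolerance = 1e-9)
  # brute-force least-squares oracle agrees
  expect_true(same_topology(tr, best_topology_by_ls(m)))

  set.seed(62)
  for (n in 4:8) {
    t0 <- ape::rtree(n)
    t0$edge.length <- runif(nrow(t0$edge), 0.5, 3)  # safely additive
    D <- tree_distance_matrix(t0)
    tr <- nj_tree(D)
    expect_true(same_topology(tr, t0))
    expect_equal(cophenetic(tr)[rownames(D), rownames(D)], D,
                 tolerance = 1e-9)
    if (n <= 5)
      expect_true(same_topology(tr, best_topology_by_ls(D)))
  }
})

test_that("nj_tree matches ape::nj topology on noisy matrices and clamps", {
  set.seed(63)
  for (rep in 1:5) {
    t0 <- ape::rtree(7)
    D <- tree_distance_matrix(t0)
    noisy <- D + matrix(runif(length(D), 0, 0.01), nrow(D))
    noisy <- (noisy + t(noisy)) / 2; diag(noisy) <- 0
    mine <- suppressWarnings(nj_tree(noisy))
    theirs <- ape::nj(as.dist(noisy))
    expect_true(same_topology(mine, theirs))
  }
  # a non-additive matrix forcing a negative pendant edge gets clamped
  m <- matrix(c(0, 10, 1, 10, 0, 1, 1, 1, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_warning(tr <- nj_tree(m), "clamped")
  expect_true(all(tr$edge.length >= 0))
})

test_that("phytab_gene_trees builds one NJ tree per adequate partition", {
  sim <- simulate_phytab(n_species = 6, n_genes = 2, occupancy = 1,
                         length_range = c(40, 60), mutation_rate = 0.1,
                         seed = 5)
  g <- phytab_gene_trees(sim$dataset)
  expect_s3_class(g, "gene_tree_table")
  expect_equal(names(g), c("g01", "g02"))
  expect_equal(sort(g[[1]]$tip.label), sort(unique(sim$dataset$species)))

  small <- phytab(c("A", "B"), c("tiny", "tiny"), c("u1", "u2"),
                  c("ACGT", "AGGT"))
  both <- phytab(c(small$species, sim$dataset$species),
                 c(small$partition, sim$dataset$partition),
                 c(small$uid, sim$dataset$uid),
                 c(small$sequence, sim$dataset$sequence))
  expect_warning(g2 <- phytab_gene_trees(both), "fewer than 3")
  expect_false("tiny" %in% names(g2))

  # partition processing order does not change per-partition results
  rev_d <- sim$dataset[rev(seq_len(nrow(sim$dataset))), ]
  rev_d <- phytab(rev_d$species, rev_d$partition, rev_d$uid, rev_d$sequence)
  g_rev <- phytab_gene_trees(rev_d)
  for (p in names(g))
    expect_true(same_topology(g[[p]], g_rev[[p]]))
})

test_that("gene-tree tables round trip through their tabular serialization", {
  set.seed(64)
  g <- gene_tree_table(replicate(4, ape::rtree(5), simplify = FALSE),
                       paste0("g", 1:4))
  tmp <- withr::local_tempfile()
  write_gene_tree_table(g, tmp)
  back <- read_gene_tree_table(tmp)
  expect_equal(names(back), names(g))
  for (p in names(g)) expect_true(same_topology(g[[p]], back[[p]]))
  expect_error(gene_tree_table(list(ape::rtree(4), ape::rtree(4)),
                               c("a", "a")), "duplicate partition")
})

test_that("internode distances match hand enumeration on the quartet case", {
  gt <- quartet_tree("((A,B),(C,D));")
  g <- gene_tree_table(list(gt, gt, gt), c("g1", "g2", "g3"))
  m <- internode_distance_matrix(g)
  expect_equal(m["A", "B"], 1)
  expect_equal(m["C", "D"], 1)
  for (pair in list(c("A", "C"), c("A", "D"), c("B", "C"), c("B", "D")))
    expect_equal(m[pair[1], pair[2]], 2)
  expect_equal(m, t(m))
  expect_true(all(diag(m) == 0))
})

test_that("njst returns the gene-tree topology when trees agree", {
  t0 <- quartet_tree("((A:1,B:1):1,(C:1,(D:1,E:1):1):1);")
  g <- gene_tree_table(list(t0), "g1")
  st <- njst_species_tree(g)
  expect_true(same_topology(st$tree, t0))

  set.seed(65)
  t1 <- ape::rtree(6)
  g5 <- gene_tree_table(replicate(5, t1, simplify = FALSE), paste0("g", 1:5))
  expect_true(same_topology(njst_species_tree(g5)$tree, t1))
})

test_that("njst recovers the model topology from NNI-noisy gene trees", {
  model <- quartet_tree("((A:1,B:1):1,((C:1,D:1):1,(E:1,F:1):1):1);")
  g <- simulate_gene_trees(model, n_trees = 200, swap_rate = 0.3, seed = 19)
  st <- njst_species_tree(g)
  expect_true(same_topology(st$tree, model))
  # oracle: the zero-noise run gives the model topology too
  g0 <- simulate_gene_trees(model, n_trees = 20, swap_rate = 0, seed = 19)
  expect_true(same_topology(njst_species_tree(g0)$tree, st$tree))
})

test_that("njst errors on species pairs that never co-occur", {
  g <- gene_tree_table(list(quartet_tree("((A,B),(C,D));"),
                            quartet_tree("((E,F),(G,H));")),
                       c("g1", "g2"))
  expect_error(njst_species_tree(g), "never co-occur")
})

test_that("tree_support scores bipartitions as rounded percentages", {
  ref <- quartet_tree("((A,B),(C,D));")
  ten <- replicate(10, quartet_tree("((A,B),(C,D));"), simplify = FALSE)
  sup <- tree_support(ref, ten)
  expect_true(all(sup$node.label[sup$node.label != ""] == "100"))

  mix <- c(replicate(7, quartet_tree("((A,B),(C,D));"), simplify = FALSE),
           replicate(3, quartet_tree("((A,C),(B,D));"), simplify = FALSE))
  sup2 <- tree_support(ref, mix)
  expect_equal(sup2$node.label[sup2$node.label != ""], "70")

  # invariant to input order and to rerooting of the inputs
  sup3 <- tree_support(ref, rev(mix))
  expect_equal(sup3$node.label, sup2$node.label)
  rerooted <- lapply(mix, function(t) ape::root(t, sample(t$tip.label, 1)))
  sup4 <- tree_support(ref, rerooted)
  expect_equal(sup4$node.label, sup2$node.label)

  vals <- suppressWarnings(as.integer(sup2$node.label))
  vals <- vals[!is.na(vals)]
  expect_true(all(vals >= 0 & vals <= 100))
  expect_error(tree_support(ref, list(quartet_tree("((A,B),(C,E));"))),
               "leaf set differs")
})

test_that("tree_support agrees with an independent bipartition counter", {
  set.seed(66)
  ref <- ape::rtree(7)
  trees <- replicate(25, ape::rtree(7, tip.label = sample(ref$tip.label)),
                     simplify = FALSE)
  sup <- tree_support(ref, trees)
  # oracle: ape::prop.clades on unrooted representations
  uref <- ape::unroot(ref)
  counts <- ape::prop.clades(uref, lapply(trees, ape::unroot),
                             rooted = FALSE)
  counts[is.na(counts)] <- 0
  mine <- suppressWarnings(as.integer(sup$node.label))
  theirs <- round(100 * counts / length(trees))
  # compare on non-root internal nodes (root has no edge/support)
  expect_equal(mine[-1], theirs[-1])
})

test_that("long_branch_report flags by rule and matches brute force", {
  tr <- quartet_tree("(A:1,B:1,C:10);")
  res <- long_branch_report(gene_tree_table(list(tr), "g1"),
                            mode = "factor-of-mean", threshold = 2)
  expect_equal(res$report$leaf, "C")
  expect_equal(res$report$tree_mean, 4)
  expect_equal(res$flagged_partitions, "g1")

  none <- long_branch_report(gene_tree_table(list(tr), "g1"),
                             mode = "absolute", threshold = 100)
  expect_equal(nrow(none$report), 0)
  expect_length(none$flagged_partitions, 0)

  set.seed(67)
  trees <- lapply(1:12, function(i) {
    t <- ape::rtree(6)
    t$edge.length <- runif(nrow(t$edge), 0.5, 1.5)
    if (i %% 3 == 0) {    # plant a 10x terminal branch
      term <- which(t$edge[, 2] <= 6)
      t$edge.length[term[1]] <- 10 * mean(t$edge.length[term])
    }
    t
  })
  g <- gene_tree_table(trees, paste0("g", 1:12))
  res2 <- long_branch_report(g, "factor-of-mean", 3)
  # brute-force recomputation
  expected <- unlist(lapply(names(g), function(p) {
    t <- g[[p]]
    term <- t$edge[, 2] <= length(t$tip.label)
    len <- t$edge.length[term]
    t$tip.label[t$edge[term, 2]][len > 3 * mean(len)]
  }))
  expect_setequal(paste(res2$report$partition, res2$report$leaf),
                  unlist(lapply(names(g), function(p) {
                    t <- g[[p]]
                    term <- t$edge[, 2] <= length(t$tip.label)
                    len <- t$edge.length[term]
                    leafs <- t$tip.label[t$edge[term, 2]]
                    hit <- len > 3 * mean(len)
                    paste(rep(p, sum(hit)), leafs[hit])
                  })))
  expect_setequal(res2$report$leaf, expected)
})

test_that("prune_taxa merges branch lengths and preserves patristic distances", {
  tr <- parse_trees("((A:1,B:1):1,C:2);")[[1]]
  pruned <- prune_taxa(tr, "B")
  D <- cophenetic(pruned)
  expect_equal(D["A", "C"], 4)  # 1+1 merged through the suppressed node

  set.seed(68)
  for (rep in 1:5) {
    t0 <- ape::rtree(9)
    drop <- sample(t0$tip.label, 3)
    keep <- setdiff(t0$tip.label, drop)
    before <- cophenetic(t0)[keep, keep]
    after <- cophenetic(prune_taxa(t0, drop))[keep, keep]
    expect_equal(after, before, tolerance = 1e-12)
  }
  expect_warning(prune_taxa(ape::rtree(5), c("t1", "nosuch")), "not in tree")
  expect_error(prune_taxa(ape::rtree(3), c("t1", "t2")), "fewer than 2")
})

test_that("thin_trees keeps every step-th tree starting at the first", {
  trees <- structure(replicate(10, ape::rtree(4), simplify = FALSE),
                     class = "multiPhylo")
  thinned <- thin_trees(trees, 2)
  expect_length(thinned, 5)
  for (k in 1:5) expect_identical(thinned[[k]], trees[[2 * k - 1]])
  expect_length(thin_trees(trees, 1), 10)
})

test_that("pd_pairs sums path lengths; all-pairs obeys the four-point rule", {
  tr <- parse_trees("(A:1,(B:2,C:3):4);")[[1]]
  pd <- pd_pairs(tr)
  get <- function(a, b) pd$distance[(pd$a == a & pd$b == b) |
                                    (pd$a == b & pd$b == a)]
  expect_equal(get("A", "B"), 7)
  expect_equal(get("B", "C"), 5)
  expect_equal(get("A", "C"), 8)
  expect_equal(nrow(pd), 3)
  expect_equal(pd_pairs(tr, rbind(c("A", "A")))$distance, 0)
  expect_error(pd_pairs(tr, rbind(c("A", "Z"))), "unknown leaf")

  set.seed(69)
  for (rep in 1:5) {
    t0 <- ape::rtree(8)
    pd <- pd_pairs(t0)
    expect_equal(nrow(pd), 8 * 7 / 2)
    D <- matrix(0, 8, 8, dimnames = list(t0$tip.label, t0$tip.label))
    D[cbind(pd$a, pd$b)] <- pd$distance
    D <- D + t(D)
    quads <- utils::combn(t0$tip.label, 4)
    for (q in seq_len(ncol(quads))) {
      x <- quads[, q]
      sums <- sort(c(D[x[1], x[2]] + D[x[3], x[4]],
                     D[x[1], x[3]] + D[x[2], x[4]],
                     D[x[1], x[4]] + D[x[2], x[3]]))
      expect_lt(sums[3] - sums[2], 1e-9)
    }
  }
})
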
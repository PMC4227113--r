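# Deterministic synthetic data: uneven-coverage phytab datasets and
# NNI-perturbed gene-tree sets. One explicit integer seed drives each
# generator; the caller's global RNG state is saved and restored so the
# simulators never leak random state.

with_local_seed <- function(seed, expr) {
  if (is.null(seed)) stop("a seed is required for reproducible simulation")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

sim_alphabet <- function(alphabet) {
  switch(alphabet,
         dna = c("A", "C", "G", "T"),
         protein = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
         morphology = c("0", "1"),
         stop("unknown alphabet: ", alphabet))
}

#' Simulate an uneven-coverage phytab dataset
#'
#' Emulates a multi-gene dataset with patchy taxon sampling, the situation
#' supermatrix coverage filtering exists for. For each gene a random
#' ancestral sequence is drawn with length uniform over
#' \code{length_range}; each species carries the gene independently with
#' probability \code{occupancy}, and present copies are mutated at
#' \code{mutation_rate} per site (substitution to a different symbol, no
#' indels, so each gene stays aligned at uniform length). Identical
#' arguments and seed give byte-identical output.
#'
#' @param n_species,n_genes counts (>= 1).
#' @param occupancy per-(species, gene) presence probability in \[0, 1\].
#' @param length_range two integers, inclusive gene-length bounds.
#' @param alphabet \code{"dna"}, \code{"protein"} or \code{"morphology"}.
#' @param mutation_rate per-site substitution probability in \[0, 1\].
#' @param seed integer RNG seed (required).
#' @return list with \code{dataset} (phytab; records grouped by gene, one
#'   per present species) and \code{coverage} (true
#'   \code{"coverage_matrix"}: genes x species presence grid, lengths,
#'   default models).
#' @export
simulate_phytab <- function(n_species = 20, n_genes = 10, occupancy = 0.6,
                            length_range = c(100, 400), alphabet = "dna",
                            mutation_rate = 0.05, seed) {
  stopifnot(n_species >= 1, n_genes >= 1, occupancy >= 0, occupancy <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            length(length_range) == 2, length_range[1] >= 1,
            length_range[1] <= length_range[2])
  chars <- sim_alphabet(alphabet)
  species <- sprintf("sp%02d", seq_len(n_species))
  genes <- sprintf("g%02d", seq_len(n_genes))
  with_local_seed(seed, {
    recs <- list()
    presence <- matrix(FALSE, n_genes, n_species,
                       dimnames = list(genes, species))
    lens <- stats::setNames(integer(n_genes), genes)
    for (gi in seq_len(n_genes)) {
      len <- sample(seq(length_range[1], length_range[2]), 1L)
      lens[gi] <- len
      anc <- sample(chars, len, replace = TRUE)
      for (si in seq_len(n_species)) {
        if (stats::runif(1) >= occupancy) next
        presence[gi, si] <- TRUE
        seq <- anc
        mut <- which(stats::runif(len) < mutation_rate)
        if (length(mut)) {
          seq[mut] <- vapply(seq[mut], function(ch)
            sample(setdiff(chars, ch), 1L), character(1))
        }
        recs[[length(recs) + 1L]] <- c(species[si], genes[gi],
                                       paste0(species[si], "_", genes[gi]),
                                       paste(seq, collapse = ""))
      }
    }
    m <- do.call(rbind, recs)
    d <- if (is.null(m)) phytab(provenance = "simulate_phytab")
         else phytab(m[, 1], m[, 2], m[, 3], m[, 4],
                     provenance = sprintf("simulate_phytab(seed=%d)", seed))
    models <- stats::setNames(
      rep(if (alphabet == "dna") "GTR" else "WAG", n_genes), genes)
    cov <- structure(list(presence = presence, lengths = lens,
                          models = models), class = "coverage_matrix")
    list(dataset = d, coverage = cov)
  })
}

#' Simulate gene trees around a model species tree
#'
#' Each simulated tree starts as a copy of \code{model_tree}; with
#' probability \code{swap_rate} one random nearest-neighbor interchange
#' (NNI) is applied, giving controlled topological noise with a checkable
#' expected agreement rate of \code{1 - swap_rate}. Branch lengths are
#' resampled i.i.d. from a lognormal (meanlog \code{log(0.1)}, sdlog 0.5 by
#' default -- typical gene-tree branch-length scale and spread). Identical
#' arguments and seed reproduce the set exactly.
#'
#' @param model_tree a \code{phylo} with at least 4 leaves.
#' @param n_trees number of gene trees.
#' @param swap_rate per-tree NNI probability in \[0, 1\].
#' @param seed integer RNG seed (required).
#' @param bl_meanlog,bl_sdlog lognormal parameters for branch lengths.
#' @return a [gene_tree_table()] with partitions \code{g001, g002, ...}.
#' @export
simulate_gene_trees <- function(model_tree, n_trees, swap_rate, seed,
                                bl_meanlog = log(0.1), bl_sdlog = 0.5) {
  stopifnot(inherits(model_tree, "phylo"),
            length(model_tree$tip.label) >= 4,
            n_trees >= 1, swap_rate >= 0, swap_rate <= 1)
  base <- ape::unroot(model_tree)
  with_local_seed(seed, {
    trees <- lapply(seq_len(n_trees), function(i) {
      tr <- if (stats::runif(1) < swap_rate) phangorn::rNNI(base, moves = 1)
            else base
      tr$edge.length <- stats::rlnorm(nrow(tr$edge), bl_meanlog, bl_sdlog)
      tr
    })
    gene_tree_table(trees, sprintf("g%03d", seq_len(n_trees)))
  })
}
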
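# Shared fixtures, all built in code.

# Minimal genotype tibble from a per-individual genotype list:
# geno_tbl(list(ind1 = list(l1 = c(150, 152), ...), ...), pop = ...)
geno_tbl <- function(calls, pop = "popA") {
  purrr::imap_dfr(calls, function(loci, ind) {
    purrr::imap_dfr(loci, function(al, loc) {
      tibble::tibble(
        population = pop, individual = ind, locus = loc,
        allele_1 = if (anyNA(al)) NA_integer_ else min(al),
        allele_2 = if (anyNA(al)) NA_integer_ else max(al)
      )
    })
  })
}

# Two well-separated populations (skewed spectra, disjoint-ish alleles).
divergent_pair_sim <- function(n_per_pop = 25, n_loci = 20, seed = 11) {
  simulate_genotypes(pop_sim_params(
    n_populations = 2, n_individuals_per_pop = n_per_pop, n_loci = n_loci,
    alleles_per_locus = 4, freq_concentration = 0.3, seed = seed
  ))
}

# Random additive distance matrix from a random binary tree with strictly
# positive branch lengths; returns list(tree, d).
additive_fixture <- function(n_leaves, seed) {
  set.seed(seed)
  tr <- ape::unroot(ape::rtree(n_leaves))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.2, 1.5)
  list(tree = tr, d = stats::cophenetic(tr))
}

# Regular polygon approximating a circle of radius r.
circle_polygon <- function(n = 512, r = 1) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(r * cos(th), r * sin(th))
}

expect_tibble_equal <- function(a, b) {
  expect_equal(as.data.frame(a), as.data.frame(b))
}
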
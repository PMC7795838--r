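# Nei's standard distance, neighbor-joining, bootstrap supports, Newick IO.

test_that("identical frequency profiles give zero distance and the toy value checks out", {
  g <- geno_tbl(list(i1 = list(l1 = c(100, 100)),
                     i2 = list(l1 = c(100, 100))), pop = "X") |>
    dplyr::bind_rows(geno_tbl(list(j1 = list(l1 = c(100, 102)),
                                   j2 = list(l1 = c(100, 102))), pop = "Y"))
  dm <- nei_standard_distance(g, unit = "population")
  expect_equal(unname(diag(dm)), c(0, 0))
  # J_X = 1, J_Y = 0.5, J_XY = 0.5 => D = -ln(0.5/sqrt(0.5)) = ln(2)/2
  expect_equal(dm["X", "Y"], -log(0.5 / sqrt(0.5)), tolerance = 1e-12)
  expect_equal(dm["X", "Y"], 0.3466, tolerance = 1e-4)
})

test_that("Nei distance is symmetric and non-negative on simulated data", {
  sim <- simulate_genotypes(pop_sim_params(
    n_populations = 4, n_individuals_per_pop = 6, n_loci = 12,
    missing_rate = 0.05, seed = 42
  ))
  for (unit in c("population", "individual")) {
    dm <- nei_standard_distance(sim$genotypes, unit = unit, cap = 25)
    m <- unclass(dm)
    expect_lt(max(abs(m - t(m))), 1e-12)
    expect_true(all(m >= 0))
    expect_equal(unname(diag(m)), rep(0, nrow(m)))
  }
})

test_that("disjoint allele sets are infinite distances unless capped", {
  g <- geno_tbl(list(i1 = list(l1 = c(100, 100))), pop = "X") |>
    dplyr::bind_rows(geno_tbl(list(j1 = list(l1 = c(120, 120))), pop = "Y"))
  expect_error(nei_standard_distance(g, unit = "population"), "cap")
  dm <- nei_standard_distance(g, unit = "population", cap = 30)
  expect_equal(dm["X", "Y"], 30)
})

test_that("three taxa produce the closed-form star", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  lens <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[["A"]], (3 + 4 - 5) / 2)
  expect_equal(lens[["B"]], (3 + 5 - 4) / 2)
  expect_equal(lens[["C"]], (4 + 5 - 3) / 2)
})

test_that("NJ exactly recovers additive trees (Atteson consistency)", {
  for (seed in 1:5) {
    fx <- additive_fixture(6, seed)
    tr <- neighbor_joining(fx$d)
    expect_equal(ape::dist.topo(ape::unroot(tr), fx$tree), 0,
                 ignore_attr = TRUE)
    # branch lengths recovered to numerical precision
    expect_lt(
      max(abs(sort(tr$edge.length) - sort(fx$tree$edge.length))), 1e-9
    )
    # distances induced by the tree equal the input
    expect_lt(max(abs(stats::cophenetic(tr)[rownames(fx$d), colnames(fx$d)] -
                        fx$d)), 1e-9)
  }
})

test_that("NJ agrees with ape's reference implementation", {
  sim <- simulate_genotypes(pop_sim_params(
    n_populations = 3, n_individuals_per_pop = 4, n_loci = 15, seed = 77
  ))
  dm <- nei_standard_distance(sim$genotypes, unit = "individual", cap = 25)
  mine <- neighbor_joining(dm)
  ref <- ape::nj(stats::as.dist(unclass(dm)))
  expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ref)), 0,
               ignore_attr = TRUE)
  expect_equal(sort(mine$edge.length), sort(pmax(ref$edge.length, 0)),
               tolerance = 1e-9)
})

test_that("NJ matches exhaustive minimum-evolution search on 5-leaf additive matrices", {
  skip_if_not_installed("phangorn")
  topos <- phangorn::allTrees(5, rooted = FALSE,
                              tip.label = paste0("t", 1:5))
  for (seed in 11:15) {
    fx <- additive_fixture(5, seed)
    nj_tree <- neighbor_joining(fx$d)
    lens <- vapply(topos, function(tp) {
      fit <- phangorn::nnls.tree(fx$d, tp, method = "unrooted")
      sum(pmax(fit$edge.length, 0))
    }, numeric(1))
    best <- topos[[which.min(lens)]]
    expect_equal(ape::dist.topo(ape::unroot(nj_tree), best), 0,
                 ignore_attr = TRUE)
  }
})

test_that("NJ is deterministic under Q ties and rejects tiny inputs", {
  D <- matrix(1, 4, 4); diag(D) <- 0
  dimnames(D) <- list(letters[1:4], letters[1:4])
  t1 <- neighbor_joining(D)
  t2 <- neighbor_joining(D)
  expect_identical(t1$edge, t2$edge)
  expect_error(neighbor_joining(D[1:2, 1:2]), "at least 3")
  Dn <- D; Dn[1, 2] <- Dn[2, 1] <- -0.1
  expect_error(neighbor_joining(Dn), "non-negative")
})

test_that("bootstrap gives certainty for disjoint clusters and one-locus data", {
  g <- tidyr::crossing(
    tibble::tibble(individual = c("A_1", "A_2", "B_1", "B_2")),
    locus = paste0("l", 1:5)
  )
  g$population <- sub("_.*", "", g$individual)
  g$allele_1 <- ifelse(g$population == "A", 100L, 120L)
  g$allele_2 <- g$allele_1
  g <- g[, c("population", "individual", "locus", "allele_1", "allele_2")]
  bt <- bootstrap_tree(g, unit = "individual", replicates = 100, seed = 1,
                       cap = 10)
  bs <- attr(bt, "bootstrap")
  expect_equal(bs$support[!is.na(bs$support)], 100)
  # a single locus: every resample is the full dataset
  sim <- simulate_genotypes(pop_sim_params(
    n_populations = 2, n_individuals_per_pop = 4, n_loci = 1, seed = 3
  ))
  bt1 <- bootstrap_tree(sim$genotypes, unit = "individual", replicates = 25,
                        seed = 2, cap = 10)
  s1 <- attr(bt1, "bootstrap")$support
  expect_equal(s1[!is.na(s1)], rep(100, sum(!is.na(s1))))
})

test_that("bootstrap supports are invariant to unit relabeling", {
  sim <- simulate_genotypes(pop_sim_params(
    n_populations = 2, n_individuals_per_pop = 5, n_loci = 10,
    alleles_per_locus = 4, freq_concentration = 0.4, seed = 12
  ))
  g <- sim$genotypes
  support_by_split <- function(g) {
    bt <- bootstrap_tree(g, unit = "individual", replicates = 50, seed = 7,
                         cap = 25)
    keys <- sagisou:::bipartition_keys(bt)
    s <- attr(bt, "bootstrap")$support
    stats::setNames(s[!is.na(keys)], keys[!is.na(keys)])
  }
  s1 <- support_by_split(g)
  # permute individual blocks (relabels unit order, keeps locus order so the
  # seeded locus-resampling stream is unchanged)
  blocks <- split(g, g$individual)
  g2 <- dplyr::bind_rows(blocks[rev(names(blocks))])
  s2 <- support_by_split(g2)
  common <- intersect(names(s1), names(s2))
  expect_gt(length(common), 0)
  expect_equal(s1[common], s2[common])
})

test_that("newick output has the documented shape and round-trips", {
  star <- list(
    edge = matrix(c(4L, 4L, 4L, 1L, 2L, 3L), ncol = 2),
    edge.length = c(1, 2, 3),
    tip.label = c("A", "B", "C"),
    Nnode = 1L
  )
  class(star) <- "phylo"
  expect_identical(newick_string(star),
                   "(A:1.000000,B:2.000000,C:3.000000);")
  fx <- additive_fixture(7, 2)
  tr <- neighbor_joining(fx$d)
  tr$tip.label[2] <- "sample two" # space forces quoting
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path)
  expect_true(grepl("'sample two'", readLines(path)[1], fixed = TRUE))
  back <- read_newick(path)
  expect_setequal(back$tip.label, tr$tip.label)
  expect_equal(ape::dist.topo(ape::unroot(back), ape::unroot(tr)), 0,
               ignore_attr = TRUE)
  expect_equal(sort(back$edge.length), sort(tr$edge.length),
               tolerance = 1e-6)
})

test_that("stronger divergence gives non-decreasing population-split support", {
  # support of the bipartition separating the two populations, averaged
  # over seeds, under strongly vs weakly differentiated allele spectra
  pop_split_support <- function(conc, seed) {
    sim <- simulate_genotypes(pop_sim_params(
      n_populations = 2, n_individuals_per_pop = 6, n_loci = 15,
      alleles_per_locus = 4, freq_concentration = conc, seed = seed
    ))
    bt <- bootstrap_tree(sim$genotypes, unit = "individual",
                         replicates = 60, seed = seed, cap = 25)
    keys <- sagisou:::bipartition_keys(bt)
    s <- attr(bt, "bootstrap")$support
    inds <- unique(sim$genotypes$individual)
    side <- sort(grep("^pop2", inds, value = TRUE))
    key <- paste(side, collapse = "\r")
    if (key %in% keys) s[match(key, keys)] else 0
  }
  strong <- mean(vapply(1:3, function(s) pop_split_support(0.15, 500 + s),
                        numeric(1)))
  weak <- mean(vapply(1:3, function(s) pop_split_support(2.5, 500 + s),
                      numeric(1)))
  expect_gte(strong, weak)
  expect_gte(strong, 60)
})
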
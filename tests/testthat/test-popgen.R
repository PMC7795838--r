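# Diversity statistics: allele frequencies, Ho/He, F, null alleles,
# population table, screening arithmetic.

test_that("allele frequencies count both copies and exclude missing calls", {
  g <- geno_tbl(list(
    i1 = list(l1 = c(150, 150)),
    i2 = list(l1 = c(150, 150))
  ))
  af <- allele_frequencies(g)
  expect_equal(af$freq, 1)
  g2 <- geno_tbl(list(
    i1 = list(l1 = c(150, 152)),
    i2 = list(l1 = c(150, 150)),
    i3 = list(l1 = c(NA, NA))
  ))
  af2 <- allele_frequencies(g2)
  expect_equal(af2$freq[af2$allele == 150], 0.75)
  expect_equal(af2$freq[af2$allele == 152], 0.25)
  g3 <- geno_tbl(list(i1 = list(l1 = c(NA, NA))))
  expect_error(allele_frequencies(g3, "popA", "l1"), "l1")
})

test_that("estimated frequencies approach truth in a large sample", {
  sim <- simulate_genotypes(pop_sim_params(
    n_populations = 1, n_individuals_per_pop = 500, n_loci = 10,
    alleles_per_locus = 5, seed = 8
  ))
  obs <- allele_frequencies(sim$genotypes)
  j <- dplyr::inner_join(obs, sim$truth$allele_freqs,
                         by = c("population", "locus", "allele"))
  expect_lt(max(abs(j$freq.x - j$freq.y)), 0.05)
})

test_that("observed heterozygosity is the fraction of heterozygous plants", {
  g <- geno_tbl(list(
    i1 = list(l1 = c(150, 152)),
    i2 = list(l1 = c(150, 150)),
    i3 = list(l1 = c(152, 152))
  ))
  expect_equal(observed_heterozygosity(g, "popA", "l1"), 1 / 3)
  g2 <- geno_tbl(list(i1 = list(l1 = c(150, 150)),
                      i2 = list(l1 = c(152, 152))))
  expect_equal(observed_heterozygosity(g2, "popA", "l1"), 0)
})

test_that("Ho under random mating matches its binomial expectation", {
  sim <- simulate_genotypes(pop_sim_params(
    n_populations = 1, n_individuals_per_pop = 1000, n_loci = 1,
    alleles_per_locus = 2, freq_concentration = 50, seed = 17
  ))
  truth <- sim$truth$allele_freqs
  p <- truth$freq[truth$allele == 100]
  expected <- 2 * p * (1 - p)
  expect_equal(
    observed_heterozygosity(sim$genotypes, "pop1", "locus_01"),
    expected, tolerance = 0.05
  )
})

test_that("unbiased He matches the finite-sample formula and its limits", {
  g <- geno_tbl(list(
    i1 = list(l1 = c(100, 102)), i2 = list(l1 = c(100, 102)),
    i3 = list(l1 = c(100, 102)), i4 = list(l1 = c(100, 100)),
    i5 = list(l1 = c(102, 102))
  ))
  # p = (0.5, 0.5), n = 5: (10/9) * 0.5
  expect_equal(expected_heterozygosity(g, "popA", "l1"), 10 / 9 * 0.5,
               tolerance = 1e-12)
  mono <- geno_tbl(list(i1 = list(l1 = c(100, 100)),
                        i2 = list(l1 = c(100, 100))))
  expect_equal(expected_heterozygosity(mono, "popA", "l1"), 0)
  expect_error(
    expected_heterozygosity(geno_tbl(list(i1 = list(l1 = c(100, 102)))),
                            "popA", "l1"),
    "2 typed"
  )
  # k equifrequent alleles, large n: He -> (k-1)/k
  k <- 4
  n <- 2000
  al <- sagisou:::allele_sizes(k)
  g4 <- tibble::tibble(
    population = "p", individual = sprintf("p_%04d", 1:n), locus = "l1",
    allele_1 = rep(al, length.out = n), allele_2 = rep(al, length.out = n)
  )
  expect_equal(expected_heterozygosity(g4, "p", "l1"), (k - 1) / k,
               tolerance = 1e-3)
})

test_that("He estimator is unbiased at small n", {
  set.seed(55)
  truth_he <- NULL
  ests <- replicate(300, NA_real_)
  sim0 <- simulate_genotypes(pop_sim_params(
    n_populations = 1, n_individuals_per_pop = 10, n_loci = 1,
    alleles_per_locus = 3, freq_concentration = 5, seed = 1000
  ))
  p <- sim0$truth$allele_freqs$freq
  truth_he <- 1 - sum(p^2)
  # resample genotypes at the same frequencies by reusing the generator
  for (r in seq_along(ests)) {
    g <- with(list(), {
      a1 <- sample(sagisou:::allele_sizes(3), 10, TRUE, prob = p)
      a2 <- sample(sagisou:::allele_sizes(3), 10, TRUE, prob = p)
      tibble::tibble(population = "p", individual = sprintf("p_%02d", 1:10),
                     locus = "l1", allele_1 = pmin(a1, a2),
                     allele_2 = pmax(a1, a2))
    })
    ests[r] <- expected_heterozygosity(g, "p", "l1")
  }
  se <- stats::sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - truth_he), 2.5 * se + 1e-12)
})

test_that("fixation index follows the Table-1 sign convention", {
  expect_equal(fixation_index(0.5, 0.5), 0)
  expect_equal(fixation_index(0.5, 0), 1)
  expect_lt(fixation_index(0.2362, 0.4441), 0) # Ho > He => negative F
  expect_true(is.na(fixation_index(0, 0.1)))
})

test_that("null-allele estimator is the normalized het deficit", {
  expect_equal(null_allele_frequency(0.5, 0.5), 0)
  expect_equal(null_allele_frequency(0.5, 0.3), 0.25)
  expect_equal(null_allele_frequency(0.3, 0.5), -0.25)
  expect_true(is.na(null_allele_frequency(0, 0)))
})

test_that("population table recovers a Ueno-scale inbreeding coefficient", {
  fhats <- vapply(1:30, function(s) {
    sim <- simulate_genotypes(pop_sim_params(
      n_populations = 1, n_individuals_per_pop = 9, n_loci = 21,
      alleles_per_locus = 5, f_is_per_pop = 0.17, seed = 4000 + s
    ))
    st <- sagisou:::locus_stats(sim$genotypes)
    fixation_index(mean(st$he, na.rm = TRUE), mean(st$ho))
  }, numeric(1))
  expect_lt(abs(mean(fhats) - 0.17), 0.08)
})

test_that("population table reports N, means, F and permutation p per population", {
  sim <- simulate_genotypes(pop_sim_params(
    n_populations = 2, n_individuals_per_pop = c(8, 12), n_loci = 10,
    seed = 19
  ))
  pt <- population_table(sim$genotypes, reps = 199, seed = 1)
  expect_equal(pt$n, c(8L, 12L))
  expect_equal(pt$f, 1 - pt$ho_mean / pt$he_mean, tolerance = 1e-12)
  expect_true(all(pt$f_p > 0 & pt$f_p <= 1))
  expect_error(population_table(sim$genotypes[0, ]), "Empty")
})

test_that("deleting one call changes only that locus's summaries", {
  sim <- simulate_genotypes(pop_sim_params(
    n_populations = 1, n_individuals_per_pop = 15, n_loci = 5, seed = 23
  ))
  g <- sim$genotypes
  st0 <- sagisou:::locus_stats(g)
  g2 <- g
  hit <- which(g2$locus == "locus_03")[1]
  g2$allele_1[hit] <- NA_integer_
  g2$allele_2[hit] <- NA_integer_
  st1 <- sagisou:::locus_stats(g2)
  changed <- st0$locus[abs(st0$he - st1$he) > 1e-15 |
                         abs(st0$ho - st1$ho) > 1e-15 |
                         st0$n_typed != st1$n_typed]
  expect_identical(changed, "locus_03")
})

test_that("screening percentage reproduces the library arithmetic", {
  expect_identical(marker_screening_summary(107, 144), 74.3)
  expect_identical(marker_screening_summary(0, 10), 0)
  expect_identical(marker_screening_summary(10, 10), 100)
  expect_error(marker_screening_summary(5, 0), "positive count")
  expect_error(marker_screening_summary(11, 10), "between")
})
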
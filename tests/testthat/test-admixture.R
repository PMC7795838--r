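# Admixture Gibbs sampler, likelihood, ln P(D), parameter recovery.

test_that("K = 1 is the degenerate single-cluster model", {
  sim <- divergent_pair_sim(n_per_pop = 6, n_loci = 5)
  fit <- run_admixture_mcmc(sim$genotypes, k = 1, burn_in = 100, reps = 400,
                            thin = 5, seed = 2)
  expect_true(all(fit$q == 1))
  expect_true(is.finite(fit$ln_prob_data))
  expect_lte(fit$ln_prob_data, max(fit$lnL_trace))
})

test_that("well-separated populations are assigned cleanly at K = 2", {
  sim <- divergent_pair_sim(n_per_pop = 20, n_loci = 20)
  fit <- run_admixture_mcmc(sim$genotypes, k = 2, burn_in = 1000,
                            reps = 4000, thin = 10, seed = 5)
  expect_equal(unname(rowSums(fit$q)), rep(1, nrow(fit$q)), tolerance = 1e-9)
  expect_gt(min(apply(fit$q, 1, max)), 0.95)
  # the two populations land in different clusters
  dom <- apply(fit$q, 1, which.max)
  pops <- fit$populations
  expect_identical(length(unique(dom[pops == "pop1"])), 1L)
  expect_false(dom[pops == "pop1"][1] == dom[pops == "pop2"][1])
})

test_that("chains are deterministic given seed and config", {
  sim <- divergent_pair_sim(n_per_pop = 6, n_loci = 5)
  f1 <- run_admixture_mcmc(sim$genotypes, k = 2, burn_in = 100, reps = 300,
                           seed = 9)
  f2 <- run_admixture_mcmc(sim$genotypes, k = 2, burn_in = 100, reps = 300,
                           seed = 9)
  expect_identical(f1$lnL_trace, f2$lnL_trace)
  expect_identical(f1$q, f2$q)
  f3 <- run_admixture_mcmc(sim$genotypes, k = 2, burn_in = 100, reps = 300,
                           seed = 10)
  expect_false(identical(f1$lnL_trace, f3$lnL_trace))
})

test_that("a constructed half-and-half admixed plant is recovered", {
  set.seed(101)
  sim <- divergent_pair_sim(n_per_pop = 20, n_loci = 20, seed = 31)
  truth <- sim$truth$allele_freqs
  loci <- unique(truth$locus)
  mixed <- purrr::map_dfr(loci, function(l) {
    p1 <- truth[truth$population == "pop1" & truth$locus == l, ]
    p2 <- truth[truth$population == "pop2" & truth$locus == l, ]
    a <- sample(p1$allele, 1, prob = p1$freq)
    b <- sample(p2$allele, 1, prob = p2$freq)
    tibble::tibble(population = "mix", individual = "mix_01", locus = l,
                   allele_1 = min(a, b), allele_2 = max(a, b))
  })
  g <- dplyr::bind_rows(sim$genotypes, mixed)
  fit <- run_admixture_mcmc(g, k = 2, burn_in = 1500, reps = 6000,
                            thin = 10, seed = 3)
  qmix <- fit$q["mix_01", ]
  expect_lt(max(abs(qmix - 0.5)), 0.15)
})

test_that("log-likelihood matches hand computation and doubles under duplication", {
  g <- geno_tbl(list(i1 = list(l1 = c(100, 100))))
  p <- list(l1 = matrix(0.5, 1, 1, dimnames = list("cluster_1", "100")))
  q <- matrix(1, 1, 1, dimnames = list("i1", "cluster_1"))
  expect_equal(log_likelihood(g, p, q), log(0.25))
  sim <- divergent_pair_sim(n_per_pop = 5, n_loci = 5)
  fit <- run_admixture_mcmc(sim$genotypes, k = 2, burn_in = 100, reps = 300,
                            seed = 4)
  ll1 <- log_likelihood(sim$genotypes, fit$p, fit$q)
  dup <- sim$genotypes
  dup$individual <- paste0(dup$individual, "_copy")
  qdup <- fit$q
  rownames(qdup) <- paste0(rownames(qdup), "_copy")
  ll2 <- log_likelihood(dplyr::bind_rows(sim$genotypes, dup), fit$p,
                        rbind(fit$q, qdup))
  expect_equal(ll2, 2 * ll1, tolerance = 1e-9)
})

test_that("log-likelihood agrees with per-copy brute force on a random instance", {
  sim <- divergent_pair_sim(n_per_pop = 4, n_loci = 4, seed = 8)
  fit <- run_admixture_mcmc(sim$genotypes, k = 2, burn_in = 50, reps = 200,
                            seed = 6)
  g <- sim$genotypes[!is.na(sim$genotypes$allele_1), ]
  brute <- 0
  for (r in seq_len(nrow(g))) {
    for (al in c(g$allele_1[r], g$allele_2[r])) {
      pm <- fit$p[[g$locus[r]]]
      pk <- pm[, as.character(al)]
      qi <- fit$q[g$individual[r], ]
      brute <- brute + log(sum(qi * pk))
    }
  }
  expect_equal(log_likelihood(g, fit$p, fit$q), brute, tolerance = 1e-10)
})

test_that("zero-probability alleles are flagged as -Inf", {
  g <- geno_tbl(list(i1 = list(l1 = c(100, 104))))
  p <- list(l1 = matrix(c(1, 0), 1, 2,
                        dimnames = list("cluster_1", c("100", "104"))))
  q <- matrix(1, 1, 1, dimnames = list("i1", "cluster_1"))
  expect_warning(ll <- log_likelihood(g, p, q), "zero probability")
  expect_identical(ll, -Inf)
})

test_that("relabeling clusters leaves the likelihood unchanged", {
  sim <- divergent_pair_sim(n_per_pop = 5, n_loci = 5)
  fit <- run_admixture_mcmc(sim$genotypes, k = 3, burn_in = 100, reps = 300,
                            seed = 11)
  perm <- c(3, 1, 2)
  p_perm <- lapply(fit$p, function(m) m[perm, , drop = FALSE])
  q_perm <- fit$q[, perm, drop = FALSE]
  expect_equal(log_likelihood(sim$genotypes, fit$p, fit$q),
               log_likelihood(sim$genotypes, p_perm, q_perm),
               tolerance = 1e-12)
})

test_that("ln P(D) estimator follows the mean-minus-half-variance formula", {
  expect_equal(estimate_ln_prob_data(rep(-7.5, 10)), -7.5)
  expect_equal(estimate_ln_prob_data(c(-10, -12)), -12) # mean -11, var 2
  tr <- c(-10, -12, -11, -14)
  expect_equal(estimate_ln_prob_data(tr + 5), estimate_ln_prob_data(tr) + 5)
  expect_error(estimate_ln_prob_data(-3), "length >= 2")
})

test_that("missing calls are skipped, not imputed", {
  sim <- divergent_pair_sim(n_per_pop = 8, n_loci = 8)
  g <- sim$genotypes
  miss <- withr::with_seed(2, sample(nrow(g), 10))
  g$allele_1[miss] <- NA_integer_
  g$allele_2[miss] <- NA_integer_
  fit <- run_admixture_mcmc(g, k = 2, burn_in = 200, reps = 600, seed = 13)
  expect_equal(unname(rowSums(fit$q)), rep(1, nrow(fit$q)), tolerance = 1e-9)
  expect_true(all(is.finite(fit$lnL_trace)))
})
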
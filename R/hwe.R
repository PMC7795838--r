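# Exact Hardy-Weinberg testing conditional on allele counts, and the
# permutation test for the multi-locus fixation index.

# Canonical internal form: list(k, pairs matrix [i, j] with i <= j, counts).
as_genotype_counts <- function(x) {
  if (is.data.frame(x) && all(c("allele_1", "allele_2") %in% names(x))) {
    calls <- x[!is.na(x$allele_1) & !is.na(x$allele_2), ]
    if (nrow(calls) == 0L) abort("No non-missing genotype calls.")
    alleles <- sort(unique(c(calls$allele_1, calls$allele_2)))
    i <- match(pmin(calls$allele_1, calls$allele_2), alleles)
    j <- match(pmax(calls$allele_1, calls$allele_2), alleles)
    k <- length(alleles)
    counts <- matrix(0L, k, k, dimnames = list(alleles, alleles))
    for (r in seq_along(i)) counts[i[r], j[r]] <- counts[i[r], j[r]] + 1L
    d <- diag(counts)
    counts <- counts + t(counts)
    diag(counts) <- d
    return(counts)
  }
  if (is.matrix(x)) {
    if (nrow(x) != ncol(x)) abort("Genotype count matrix must be square.")
    if (any(x < 0) || any(x != round(x))) {
      abort("Genotype counts must be non-negative integers.")
    }
    up <- x[upper.tri(x)]
    lo <- t(x)[upper.tri(x)]
    if (any(up != 0) && any(lo != 0) && any(up != lo)) {
      abort("Genotype count matrix must be symmetric (or triangular).")
    }
    if (all(lo == 0) || all(up == 0)) {
      x[upper.tri(x)] <- pmax(up, lo)
      x[lower.tri(x)] <- t(x)[lower.tri(x)]
    }
    return(x)
  }
  abort("Supply a square genotype count matrix or a data frame with allele_1/allele_2.")
}

# log P(table | allele counts) for the conditional exact HWE null:
# P = N! / prod(n_ij!) * 2^het * prod(m_a!) / (2N)!
hwe_log_prob <- function(diag_counts, het_counts, m) {
  N <- sum(diag_counts) + sum(het_counts)
  lfactorial(N) - sum(lfactorial(diag_counts)) - sum(lfactorial(het_counts)) +
    sum(het_counts) * log(2) + sum(lfactorial(m)) - lfactorial(2 * N)
}

# Enumerate all genotype tables conditional on allele copy counts m.
# Recurses over heterozygote cells; homozygote counts are then forced.
# Returns a vector of log-probabilities, or NULL if more than `cap` tables.
enumerate_hwe_tables <- function(m, cap = 1e6) {
  k <- length(m)
  het_cells <- if (k >= 2) which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
               else matrix(integer(), 0, 2)
  n_cells <- nrow(het_cells)
  logps <- new.env(parent = emptyenv())
  logps$v <- numeric(0)
  logps$count <- 0L
  het <- integer(n_cells)
  recurse <- function(cell, rem) {
    if (logps$count > cap) return(FALSE)
    if (cell > n_cells) {
      if (any(rem %% 2 != 0)) return(TRUE)
      diag_counts <- rem %/% 2
      logps$v <- c(logps$v,
                   hwe_log_prob(diag_counts, het, m))
      logps$count <- logps$count + 1L
      return(TRUE)
    }
    i <- het_cells[cell, 1]; j <- het_cells[cell, 2]
    for (c in 0:min(rem[i], rem[j])) {
      het[cell] <<- c
      rem2 <- rem
      rem2[i] <- rem2[i] - c
      rem2[j] <- rem2[j] - c
      if (!recurse(cell + 1L, rem2)) return(FALSE)
    }
    het[cell] <<- 0L
    TRUE
  }
  ok <- recurse(1L, m)
  if (!ok) NULL else logps$v
}

#' Exact Hardy-Weinberg test at one locus
#'
#' Conditional-on-allele-counts exact test: the probability of a genotype
#' table given the allele counts is
#' `P = N! / prod(n_ij!) * 2^het * prod(m_a!) / (2N)!`, and the p-value is
#' the total probability of tables no more probable than the observed one.
#' All tables are enumerated when their number does not exceed
#' `max_tables`; otherwise `reps` seeded Monte-Carlo permutations of the
#' allele vector are used. A monomorphic locus returns p = 1.
#'
#' @param x Square genotype count matrix (alleles x alleles, symmetric or
#'   triangular) or a data frame with `allele_1`/`allele_2` columns.
#' @param method `"auto"` (enumerate when feasible), `"enumerate"` or
#'   `"montecarlo"`.
#' @param reps Monte-Carlo permutations.
#' @param seed Integer seed (Monte-Carlo only).
#' @param max_tables Enumeration feasibility cap (number of tables).
#' @return p-value in (0, 1\].
#' @export
#' @examples
#' # two heterozygote-free individuals: AA and aa
#' counts <- matrix(c(1, 0, 0, 1), 2, 2)
#' hwe_exact_test(counts) # 1/3
hwe_exact_test <- function(x, method = c("auto", "enumerate", "montecarlo"),
                           reps = 10000, seed = 1L, max_tables = 1e6) {
  method <- match.arg(method)
  counts <- as_genotype_counts(x)
  k <- nrow(counts)
  if (k < 2L) return(1)
  m <- as.integer(rowSums(counts) + diag(counts)) # allele copy counts
  stopifnot(sum(m) %% 2 == 0)
  obs_logp <- hwe_log_prob(diag(counts), counts[upper.tri(counts)], m)
  tol <- 1e-9 * abs(obs_logp) + 1e-12
  if (method != "montecarlo") {
    logps <- enumerate_hwe_tables(m, cap = max_tables)
    if (!is.null(logps)) {
      probs <- exp(logps)
      total <- sum(probs)
      if (abs(total - 1) > 1e-6) {
        abort("Enumerated table probabilities do not sum to 1; invalid counts.")
      }
      return(min(1, sum(probs[logps <= obs_logp + tol]) / total))
    }
    if (method == "enumerate") {
      abort(sprintf(
        "More than %g tables to enumerate; use method = 'montecarlo'.",
        max_tables
      ))
    }
  }
  # Monte Carlo: permute the allele vector and re-pair copies
  if (reps < 1) abort("`reps` must be >= 1 for Monte-Carlo testing.")
  v <- rep(seq_len(k), m)
  N <- length(v) / 2
  with_seed(seed, {
    b <- 0L
    for (r in seq_len(reps)) {
      perm <- sample(v)
      i <- pmin(perm[1:N], perm[(N + 1):(2 * N)])
      j <- pmax(perm[1:N], perm[(N + 1):(2 * N)])
      het_mask <- i != j
      cell <- (j - 1L) * k + i
      tab <- tabulate(cell, nbins = k * k)
      logp <- lfactorial(N) - sum(lfactorial(tab)) +
        sum(het_mask) * log(2) + sum(lfactorial(m)) - lfactorial(2 * N)
      if (logp <= obs_logp + tol) b <- b + 1L
    }
    (b + 1) / (reps + 1)
  })
}

#' Permutation test for the multi-locus fixation index
#'
#' Under the null of Hardy-Weinberg proportions, allele copies are permuted
#' among typed individuals within the population, independently per locus;
#' F is recomputed each replicate from locus-averaged He and Ho (He is
#' invariant under within-locus permutation, so only Ho varies). Two-sided
#' p-value with add-one correction: `p = (b + 1) / (reps + 1)` where `b`
#' counts replicates with `|F_perm| >= |F_obs|`.
#'
#' @inheritParams allele_frequencies
#' @param population Population to test.
#' @param reps Permutation replicates (>= 100).
#' @param seed Integer seed.
#' @return p-value.
#' @export
f_significance_test <- function(genotypes, population, reps = 1000,
                                seed = 1L) {
  assert_genotype_tibble(genotypes)
  if (reps < 100) abort("`reps` must be at least 100.")
  g <- drop_missing_calls(genotypes[genotypes$population == population, ])
  if (nrow(g) == 0L) abort(sprintf("Population %s has no typed calls.", population))
  st <- locus_stats(g)
  he_mean <- mean(st$he, na.rm = TRUE)
  if (!is.finite(he_mean) || he_mean <= 0) {
    abort("Locus-averaged He is zero: F and its test are undefined.")
  }
  f_obs <- 1 - mean(st$ho) / he_mean
  loci <- split(g, g$locus)
  copies <- lapply(loci, function(d) c(d$allele_1, d$allele_2))
  nl <- vapply(loci, nrow, integer(1))
  with_seed(seed, {
    b <- 0L
    for (r in seq_len(reps)) {
      ho_perm <- vapply(seq_along(copies), function(li) {
        v <- sample(copies[[li]])
        n <- nl[li]
        mean(v[1:n] != v[(n + 1):(2 * n)])
      }, numeric(1))
      f_perm <- 1 - mean(ho_perm) / he_mean
      if (abs(f_perm) >= abs(f_obs) - 1e-12) b <- b + 1L
    }
    (b + 1) / (reps + 1)
  })
}
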